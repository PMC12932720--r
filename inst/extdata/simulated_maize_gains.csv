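cycle,index,gain_T1,gain_T2,gain_T3,gain_T4
1,LPSI,10.4,-5.5,3.8,2.0
2,LPSI,10.1,-4.4,3.7,2.0
3,LPSI,9.9,-4.1,3.3,1.7
4,LPSI,10.9,-4.3,2.6,1.4
5,LPSI,10.6,-3.5,3.0,1.5
6,LPSI,10.0,-3.5,2.5,1.4
7,LPSI,5.0,-2.0,1.7,1.4
8,LPSI,5.6,-1.6,1.2,1.6
9,LPSI,5.2,-1.5,0.8,1.4
10,LPSI,4.9,-1.6,1.3,1.0
1,LGSI,8.6,-4.7,3.3,1.8
2,LGSI,8.8,-3.6,3.4,2.2
3,LGSI,8.3,-4.0,2.9,2.6
4,LGSI,9.7,-4.6,3.1,1.8
5,LGSI,9.8,-4.5,3.3,1.9
6,LGSI,9.0,-3.2,3.2,2.1
7,LGSI,7.9,-4.7,2.9,2.4
8,LGSI,6.5,-0.8,0.8,1.5
9,LGSI,6.5,-0.5,0.9,1.2
10,LGSI,7.1,-0.5,1.0,0.9
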