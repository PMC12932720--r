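cycle,index,R,scor,sr_mspe
1,QPSI,163.4,0.844,40.0
2,QPSI,145.2,0.823,38.3
3,QPSI,122.9,0.798,35.2
4,QPSI,130.2,0.801,36.9
5,QPSI,121.6,0.795,35.2
6,QPSI,100.9,0.761,32.2
7,QPSI,87.9,0.750,28.9
8,QPSI,55.3,0.903,10.3
9,QPSI,46.7,0.888,9.5
10,QPSI,42.6,0.882,8.9
1,QGSI,153.5,0.745,4.0
2,QGSI,158.0,0.730,4.0
3,QGSI,149.9,0.670,4.6
4,QGSI,171.5,0.791,3.6
5,QGSI,182.7,0.796,3.6
6,QGSI,157.3,0.724,4.3
7,QGSI,144.1,0.695,4.0
8,QGSI,82.8,0.997,1.4
9,QGSI,78.2,0.998,1.2
10,QGSI,80.7,0.996,1.3
1,LPSI,19.1,0.942,2.7
2,LPSI,17.1,0.928,2.7
3,LPSI,15.7,0.916,2.7
4,LPSI,15.9,0.917,2.7
5,LPSI,15.2,0.911,2.7
6,LPSI,13.7,0.893,2.7
7,LPSI,13.2,0.890,2.6
8,LPSI,8.8,0.942,1.2
9,LPSI,7.3,0.916,1.3
10,LPSI,7.3,0.920,1.2
1,LGSI,18.4,0.874,4.0
2,LGSI,18.0,0.866,4.0
3,LGSI,17.8,0.832,4.6
4,LGSI,19.2,0.900,3.6
5,LGSI,19.5,0.907,3.6
6,LGSI,17.5,0.842,4.3
7,LGSI,17.9,0.866,4.0
8,LGSI,9.6,0.998,1.4
9,LGSI,9.1,0.996,1.2
10,LGSI,9.5,0.995,1.3
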