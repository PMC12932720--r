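dataset,cycle,engine,index,R
JDMexico,0,ML,QPSI,59.7
JDMexico,0,ML,LPSI,5.9
JDMexico,1,ML,QGSI,35.8
JDMexico,1,ML,LGSI,3.9
JDMexico,1,Gaussian,QGSI,67.0
JDMexico,1,Gaussian,LGSI,8.4
JDMexico,2,ML,QGSI,37.0
JDMexico,2,ML,LGSI,4.1
JDMexico,2,Gaussian,QGSI,69.0
JDMexico,2,Gaussian,LGSI,8.3
JDZimbabwe,0,ML,QPSI,46.7
JDZimbabwe,0,ML,LPSI,7.8
JDZimbabwe,1,ML,QGSI,34.1
JDZimbabwe,1,ML,LGSI,6.9
JDZimbabwe,1,Gaussian,QGSI,95.8
JDZimbabwe,1,Gaussian,LGSI,4.6
JDZimbabwe,2,ML,QGSI,37.1
JDZimbabwe,2,ML,LGSI,7.3
JDZimbabwe,2,Gaussian,QGSI,90.8
JDZimbabwe,2,Gaussian,LGSI,4.5
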