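# Previously reported GA-MLR QSRR models for the five McReynolds constants: slopes b (+/- standard error) and standardised slopes b'
response,term,estimate,std_error,std_coef
X,(Intercept),-1996,203,NA
X,RBN,3.83,0.13,0.93
X,Mor10m,-4.6,0.9,-0.08
X,R3u+,-4327,1725,-0.06
X,BLTF96,-1.7,0.8,-0.05
X,SpMAD_AEA(bo),1132,136,0.19
X,H5u,22,6,0.07
Y,(Intercept),-3861,234,NA
Y,RBN,199,41,0.86
Y,SpMAD_AEA(dm),5.18,0.11,0.14
Y,Mor12m,-4.4,0.9,-0.07
Y,R3u+,-10190,1998,-0.08
Y,SpMAD_AEA(bo),2190,175,0.24
Y,H5u,22,7,0.04
Z,(Intercept),-89,23,NA
Z,RBN,4.7,0.1,0.92
Z,SpMax_B(s),18,2,0.13
Z,MATS7i,1635,270,0.14
Z,Mor02v,-0.7,0.2,-0.07
Z,Mor04p,2.1,0.5,0.08
Z,B04[N-Si],87,9,0.19
U,(Intercept),-87,25,NA
U,RBN,6.94,0.12,0.94
U,SpMax_B(s),18,3,0.09
U,MATS7i,2449,283,0.17
U,Mor02v,-0.9,0.2,-0.07
U,Mor04p,2.9,0.5,0.08
U,B04[N-Si],133,10,0.21
S,(Intercept),-4119,173,NA
S,RBN,6.16,0.09,0.98
S,SpMAD_AEA(bo),2543,111,0.29
S,Mor10v,-6.6,1.4,-0.05
S,Mor04p,2.0,0.3,0.06
S,H5u,19,5,0.05
S,R3u+,-14847,1723,-0.13
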