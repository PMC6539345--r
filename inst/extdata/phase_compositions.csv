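# Comonomer composition (mole percent) of 29 poly(siloxane) phases; pct_model is the 20-unit geometric-model composition where it differs from nominal
code,unit,pct_nominal,pct_model
OV-1,dimethyl,100,100
SE-52,dimethyl,95,95
SE-52,methylphenyl,5,5
OV-3,dimethyl,80,80
OV-3,methylphenyl,20,20
OV-7,dimethyl,60,60
OV-7,methylphenyl,40,40
DC-550,dimethyl,50,50
DC-550,methylphenyl,50,50
OV-11,dimethyl,30,30
OV-11,methylphenyl,70,70
OV-17,methylphenyl,100,100
SP-392,methylphenyl,90,90
SP-392,diphenyl,10,10
OV-22,methylphenyl,70,70
OV-22,diphenyl,30,30
OV-25,methylphenyl,50,50
OV-25,diphenyl,50,50
Rtx-20,dimethyl,80,80
Rtx-20,diphenyl,20,20
OV-61,dimethyl,67,70
OV-61,diphenyl,33,30
Rtx-35,dimethyl,65,65
Rtx-35,diphenyl,35,35
Rtx-65,dimethyl,35,35
Rtx-65,diphenyl,65,65
OV-210,trifluoropropylmethyl,100,100
SKIFT-50X,trifluoropropylmethyl,50,50
SKIFT-50X,dimethyl,50,50
FS-328,trifluoropropylmethyl,31,30
FS-328,dimethyl,69,70
FS-169,trifluoropropylmethyl,23,25
FS-169,dimethyl,77,75
SILAR 5CP,cyanopropylphenyl,100,100
SILAR 7CP,cyanopropylphenyl,50,50
SILAR 7CP,dicyanopropyl,50,50
SILAR 9CP,cyanopropylphenyl,20,20
SILAR 9CP,dicyanopropyl,80,80
SILAR 10CP,dicyanopropyl,100,100
OV-105,dimethyl,90,90
OV-105,cyanopropylmethyl,10,10
OV-225,methylphenyl,50,50
OV-225,cyanopropylmethyl,50,50
p-NSKT-100,cyanopropylmethyl,100,100
NPS-100,cyanoethylmethyl,100,100
NSKI-25,dimethyl,75,75
NSKI-25,cyanoethylmethyl,25,25
NSKT-33,dimethyl,67,65
NSKT-33,cyanoethylmethyl,33,35
XE-60,dimethyl,50,50
XE-60,cyanoethylmethyl,50,50
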