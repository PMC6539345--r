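# First five McReynolds constants (retention-index units) of 29 poly(siloxane) GC stationary phases
code,subgroup,X,Y,Z,U,S
OV-1,methylphenyl,16,55,44,65,42
SE-52,methylphenyl,32,72,65,98,67
OV-3,methylphenyl,44,86,81,124,88
OV-7,methylphenyl,69,113,111,171,128
DC-550,methylphenyl,74,116,117,178,135
OV-11,methylphenyl,102,142,145,219,178
OV-17,methylphenyl,119,158,162,243,202
SP-392,methylphenyl,133,169,176,258,219
OV-22,methylphenyl,160,188,191,283,253
OV-25,methylphenyl,178,204,208,305,280
Rtx-20,methylphenyl,67,116,117,174,131
OV-61,methylphenyl,101,143,142,213,174
Rtx-35,methylphenyl,101,146,151,219,202
Rtx-65,methylphenyl,125,175,183,268,220
OV-210,methyltrifluoropropyl,146,238,358,468,310
SKIFT-50X,methyltrifluoropropyl,66,132,192,247,158
FS-328,methyltrifluoropropyl,55,116,169,215,137
FS-169,methyltrifluoropropyl,46,104,149,189,118
SILAR 5CP,cyanoalkylmethylphenyl,319,495,446,637,530
SILAR 7CP,cyanoalkylmethylphenyl,440,638,605,844,673
SILAR 9CP,cyanoalkylmethylphenyl,489,725,631,913,778
SILAR 10CP,cyanoalkylmethylphenyl,523,755,659,942,801
OV-105,cyanoalkylmethylphenyl,36,108,93,139,86
OV-225,cyanoalkylmethylphenyl,228,369,338,492,386
p-NSKT-100,cyanoalkylmethylphenyl,276,461,405,584,473
NPS-100,cyanoalkylmethylphenyl,297,502,451,644,512
NSKI-25,cyanoalkylmethylphenyl,122,261,237,345,244
NSKT-33,cyanoalkylmethylphenyl,135,275,251,363,259
XE-60,cyanoalkylmethylphenyl,204,381,340,493,367
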