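# Reported calibration, external-prediction and Monte Carlo statistics of the reference QSRR models
response,r_squared,sdec,q2_external,sdep_external,mc_sdep_mean,mc_sdep_sd
X,0.9964,9,0.9944,15,12,1
Y,0.9984,9,0.9867,15,11,2
Z,0.9966,12,0.9900,18,14,5
U,0.9981,12,0.9920,21,15,4
S,0.9986,9,0.9914,19,12,5
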