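compound,family,mean_ng_g,min_ng_g,max_ng_g,sd_ng_g,mdl_ng_g
TnBP,OPE,1.91e2,2.00e-1,1.40e4,3.89e2,5.00e-2
TBOEP,OPE,9.81e3,7.40e-2,3.60e5,1.74e4,7.40e-2
TEHP,OPE,5.88e2,1.20e-1,6.40e4,8.05e2,1.20e-1
TCEP,OPE,5.38e3,7.20e-2,2.45e5,9.87e3,7.20e-2
TCiPP,OPE,9.47e3,2.00e1,3.70e5,1.76e4,1.00e-1
TDCiPP,OPE,4.34e4,5.00e0,7.40e5,1.04e5,6.70e-2
TPhP,OPE,6.06e3,2.30e-1,1.70e5,1.79e4,2.30e-1
EHDPP,OPE,3.30e3,7.80e-2,2.40e5,8.85e3,7.80e-2
BDE-28,PBDE,1.14e1,1.00e-2,1.49e3,1.28e1,3.00e-2
BDE-47,PBDE,4.41e2,1.00e-2,1.02e5,1.24e3,3.00e-3
BDE-99,PBDE,3.48e2,1.00e-2,2.25e5,5.45e2,3.00e-4
BDE-100,PBDE,1.11e2,2.00e-2,9.82e4,2.72e2,3.00e-3
BDE-153,PBDE,1.01e2,1.00e-2,1.79e4,2.15e2,1.00e-3
BDE-154,PBDE,4.07e1,1.00e-2,6.67e4,9.42e1,3.00e-3
BDE-183,PBDE,9.27e1,1.00e-2,1.28e3,2.33e2,1.00e-2
BDE-209,PBDE,1.52e4,1.00e-2,2.61e5,2.28e4,9.39e-2
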