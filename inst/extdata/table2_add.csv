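compound,family,add_ing_occupational,add_inh_occupational,add_der_occupational,add_ing_nonoccupational,add_inh_nonoccupational,add_der_nonoccupational
TnBP,OPE,3.65e-8,1.07e-14,6.75e-9,5.50e-9,1.62e-15,1.02e-9
TBOEP,OPE,1.87e-6,5.51e-13,3.79e-7,2.82e-7,8.30e-14,5.70e-8
TEHP,OPE,1.12e-7,3.30e-14,2.27e-8,1.69e-8,4.98e-15,3.42e-9
TCEP,OPE,1.03e-6,3.03e-13,2.69e-7,1.55e-7,4.56e-14,4.05e-8
TCiPP,OPE,1.81e-6,5.32e-13,4.58e-7,2.72e-7,8.01e-14,6.90e-8
TDCiPP,OPE,8.29e-6,2.44e-12,9.72e-7,1.25e-6,3.67e-13,1.46e-7
TPhP,OPE,1.16e-6,3.41e-13,2.34e-7,1.74e-7,5.13e-14,3.52e-8
EHDPP,OPE,6.32e-7,1.86e-13,1.28e-7,9.51e-8,2.80e-14,1.92e-8
BDE-28,PBDE,2.19e-9,6.43e-16,2.02e-10,3.29e-10,9.68e-17,2.02e-10
BDE-47,PBDE,8.44e-8,2.48e-14,7.79e-9,1.27e-8,3.73e-15,7.79e-9
BDE-99,PBDE,6.65e-8,1.96e-14,6.14e-9,1.00e-8,2.95e-15,6.14e-9
BDE-100,PBDE,2.12e-8,6.24e-15,1.96e-9,3.19e-9,9.39e-16,1.96e-9
BDE-153,PBDE,1.94e-8,5.70e-15,1.79e-9,2.92e-9,8.59e-16,1.79e-9
BDE-154,PBDE,7.78e-9,2.29e-15,7.18e-10,1.17e-9,3.44e-16,7.18e-10
BDE-183,PBDE,1.77e-8,5.21e-15,1.64e-9,2.67e-9,7.85e-16,1.64e-9
BDE-209,PBDE,2.90e-6,8.52e-13,2.67e-7,4.36e-7,1.28e-13,2.67e-7
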