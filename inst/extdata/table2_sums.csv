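family,add_ing_occupational,add_inh_occupational,add_der_occupational,add_ing_nonoccupational,add_inh_nonoccupational,add_der_nonoccupational
OPE,1.49e-5,4.40e-12,2.47e-6,2.25e-6,6.62e-13,3.72e-7
PBDE,3.12e-6,9.17e-13,2.88e-7,4.69e-7,1.38e-13,4.33e-8
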