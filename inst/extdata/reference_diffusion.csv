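system,temperature_C,D_water_cm2s,D_water_sd,Dxy_lipid_cm2s,Dxy_lipid_sd
UL,35,3.12e-5,0.04e-5,0.91e-7,0.05e-7
UL,65,4.16e-5,0.06e-5,4.24e-7,0.14e-7
ML,35,1.83e-5,0.09e-5,0.25e-7,0.05e-7
ML,65,2.30e-5,0.03e-5,3.94e-7,0.33e-7
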