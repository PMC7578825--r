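source,d13C_mean,d13C_sd,d15N_mean,d15N_sd,tef_d13C_mean,tef_d13C_sd,tef_d15N_mean,tef_d15N_sd
Zooplankton,-30.25,1.07,9.95,2.08,1.3,0.3,2.3,0.18
Phytoplankton,-27.94,0.24,8.21,1.13,1.3,0.3,2.3,0.18
C4_P,-13.29,0.21,4.06,1.44,1.3,0.3,2.3,0.18
Psp,-25.29,3.26,7.45,2.43,1.3,0.3,2.3,0.18
Mni,-26.97,0.66,15.95,1.32,1.3,0.3,2.3,0.18
Awo,-24.72,0.65,6.46,0.04,1.3,0.3,2.3,0.18
Lfo,-26.53,0,4.96,0,1.3,0.3,2.3,0.18
Sca,-24.16,0,9.51,0,1.3,0.3,2.3,0.18
Cfl,-30.27,0.26,11.99,0.31,1.3,0.3,2.3,0.18
Bsp,-22.28,0.34,4.42,1.02,1.3,0.3,2.3,0.18
Bde,-26.11,1.20,7.08,1.50,1.3,0.3,2.3,0.18
Sediment,-25.23,0.39,5.85,0.23,1.3,0.3,2.3,0.18
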