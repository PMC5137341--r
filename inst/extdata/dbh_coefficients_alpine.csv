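species,n,epsilon,se_epsilon,rho,se_rho,theta,se_theta,rmse_cm
All,1762,3.139,0.219,0.715,0.026,0.014,0.002,11
Abies_alba,70,0.503,0.299,1.287,0.219,0.008,0.006,8.6
Angiosperm,26,3.745,1.640,0.631,0.181,0.008,0.014,8.2
Larix_decidua,473,4.695,0.447,0.553,0.041,0.021,0.004,9.8
Picea_abies,1174,2.102,0.289,0.848,0.047,0.011,0.002,11.1
Pinus_cembra,19,1.362,3.668,1.303,1.119,0.001,0.017,12.9
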