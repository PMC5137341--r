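species,alpha,beta,gamma,delta,d0,wd,group,carbon_fraction,source
All,0.060,1,2.00,0.90,0,0.43,conifer,0.50,synthetic placeholder
Picea_abies,0.058,1,2.02,0.88,0,0.40,conifer,0.50,synthetic placeholder
Abies_alba,0.060,1,2.00,0.90,0,0.41,conifer,0.50,synthetic placeholder
Larix_decidua,0.062,1,1.98,0.92,0,0.55,conifer,0.50,synthetic placeholder
Pinus_cembra,0.055,1,1.95,0.95,0,0.42,conifer,0.50,synthetic placeholder
Pinus_nigra,0.056,1,1.97,0.93,0,0.48,conifer,0.50,synthetic placeholder
Pinus_sylvestris,0.056,1,1.97,0.93,0,0.48,conifer,0.50,synthetic placeholder
Angiosperm,0.052,1,2.05,1.00,0,0.58,angiosperm,0.48,synthetic placeholder
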