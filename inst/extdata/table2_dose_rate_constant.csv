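source,code,lambda_cgy_per_hu,unc,group
"GZP3 Co-60 channel 1 and 2",Geant4,1.115,0.004,this_work
"GZP3 Co-60 channel 1 and 2",EGSnrc,1.112,0.004,this_work
"GZP3 Co-60 channel 3",Geant4,1.116,0.004,this_work
"GZP3 Co-60 channel 3",EGSnrc,1.113,0.004,this_work
"GZP6 Co-60",MCNP,1.104,0.003,literature
"BEBIG Co-60",Geant4,1.084,0.005,literature
"Flexisource Co-60",Geant4,1.085,0.003,literature
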