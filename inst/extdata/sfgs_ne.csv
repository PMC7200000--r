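site,ld_ne,ld_lower,ld_upper,temporal_ne,temporal_lower,temporal_upper
Pacifica,13,8,24,9,8,9
Skyline,30,17,83,NA,NA,NA
Crystal Springs,10,5,23,NA,NA,NA
San Bruno,255,46,Inf,254,145,1021
Mindego,33,17,139,NA,NA,NA
Pescadero,60,23,Inf,56,49,66
Ano Nuevo,41,30,60,49,44,56
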