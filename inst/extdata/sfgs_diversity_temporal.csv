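site,year,n,ar,ho,he,pi
Pacifica,2004-2006,13,1.36,0.110,0.105,0.107
Pacifica,2018,19,1.29,0.099,0.096,0.098
San Bruno,2006-2007,13,1.39,0.112,0.113,0.118
San Bruno,2017,20,1.40,0.117,0.118,0.121
Pescadero,2005-2010,18,1.50,0.132,0.134,0.139
Pescadero,2016,18,1.46,0.130,0.132,0.136
Ano Nuevo,2005-2006,18,1.41,0.123,0.121,0.125
Ano Nuevo,2018,49,1.41,0.127,0.127,0.129
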