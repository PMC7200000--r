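site,year,n,ar,ho,he,pi
Pacifica,2018,20,1.31,0.092,0.090,0.092
Skyline,2018,17,1.41,0.123,0.123,0.127
Crystal Springs,2018,17,1.44,0.127,0.123,0.127
San Bruno,2017,20,1.42,0.114,0.114,0.117
Mindego,2016,22,1.38,0.112,0.112,0.115
Pescadero,2016,18,1.45,0.122,0.124,0.128
Ano Nuevo,2018,49,1.41,0.120,0.121,0.122
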