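site,region,longitude,latitude,isolated,na_modal
Pacifica,northern,-122.477,37.627,TRUE,47
Skyline,northern,-122.420,37.600,TRUE,48
Crystal Springs,northern,-122.420,37.564,TRUE,50
San Bruno,northern,-122.386,37.672,TRUE,1317
Mindego,southern,-122.240,37.300,TRUE,204
Pescadero,southern,-122.343,37.228,FALSE,73
Ano Nuevo,southern,-122.377,37.156,FALSE,123
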