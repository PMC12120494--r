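species_id,site01,site02,site03,site04,site05,site06,site07,site08
sp001,2,8,7,5,1,2,2,1
sp002,1,8,13,7,1,1,1,1
sp003,4,2,8,3,3,6,1,0
sp004,13,19,39,1,2,1,5,2
sp005,22,16,10,2,6,2,4,0
sp006,17,9,10,10,2,8,2,0
sp007,9,18,8,5,1,0,0,2
sp008,23,7,1,3,1,0,0,1
sp009,0,8,17,1,2,0,0,0
sp010,34,0,9,1,21,0,0,0
sp011,12,34,0,0,0,0,0,0
sp012,19,26,7,2,0,0,0,0
sp013,0,4,25,1,0,0,0,0
sp014,0,9,2,0,0,0,0,0
sp015,4,12,2,0,0,0,0,0
sp016,12,4,0,0,0,0,0,0
sp017,35,0,0,0,0,0,0,0
sp018,1,9,0,0,0,0,0,0
sp019,3,11,4,0,0,0,0,0
sp020,2,0,0,0,0,0,0,0
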