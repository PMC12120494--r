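species_id,is_passerine,is_resident,diet_guild,is_waterbird
sp001,FALSE,TRUE,carnivorous,FALSE
sp002,FALSE,TRUE,insectivorous,FALSE
sp003,FALSE,TRUE,insectivorous,FALSE
sp004,FALSE,FALSE,insectivorous,FALSE
sp005,TRUE,TRUE,granivorous,FALSE
sp006,TRUE,TRUE,other,FALSE
sp007,TRUE,TRUE,insectivorous,FALSE
sp008,TRUE,TRUE,nectarivorous,FALSE
sp009,TRUE,TRUE,omnivorous,FALSE
sp010,TRUE,TRUE,insectivorous,FALSE
sp011,TRUE,TRUE,other,FALSE
sp012,FALSE,TRUE,insectivorous,FALSE
sp013,TRUE,TRUE,insectivorous,FALSE
sp014,FALSE,TRUE,omnivorous,FALSE
sp015,TRUE,TRUE,omnivorous,FALSE
sp016,TRUE,FALSE,omnivorous,FALSE
sp017,FALSE,FALSE,carnivorous,FALSE
sp018,TRUE,FALSE,insectivorous,FALSE
sp019,FALSE,FALSE,insectivorous,FALSE
sp020,FALSE,TRUE,insectivorous,FALSE
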