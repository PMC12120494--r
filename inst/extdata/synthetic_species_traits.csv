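species_id,body_size,wing_length
sp001,26.331943540312498,83.39605176827521
sp002,37.41913197772411,112.42281953112483
sp003,22.901899256354426,78.05566294335263
sp004,32.68581413514109,67.33338960229617
sp005,33.970926932167345,109.92858261876674
sp006,47.97998269245056,76.79941514122096
sp007,38.42519345068388,107.58502931708784
sp008,28.677236529179275,86.47750478909339
sp009,43.2937679529894,111.6756188948349
sp010,27.437032056765567,97.49019053885155
sp011,37.03178586243636,116.67301402971658
sp012,21.82944196540792,86.56471599586745
sp013,53.10651424491227,133.81904130425085
sp014,16.684322465830235,47.828250863571995
sp015,27.290100850401817,113.05054982731846
sp016,27.76738680890525,75.0992675680487
sp017,21.35520460825749,83.92804976334023
sp018,30.70985401573168,110.65046449818303
sp019,21.63103825078887,56.58182484177691
sp020,13.211322874313172,76.75492817458789
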