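# Regional populations (persons) used for per-million-population rates.
# The source reports never print the populations; these values are
# back-solved from printed pmp rates so that the published rates round-trip:
#   Sicily  : 348 KT-DBD over 3 years at 23.6/pmp/year -> 4,915,254
#   NBench1 : 109 KTLD   over 3 years at  6.6/pmp/year -> 5,505,051
#   IBench2 : 354 KT-DBD over 3 years at 21.4/pmp/year -> 5,514,019
# Synthetic back-solved figures, close to the census populations of the
# three territories but not official statistics.
region,population
Sicily,4915254
NBench1,5505051
IBench2,5514019
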