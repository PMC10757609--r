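# Published utilized-donor (UD) rates per million population by year.
# Absolute UD counts are not published for the study regions; these rates
# are reference data, not inputs to the savings model.
# dbd/dcd split not published for Sicily and NBench1 before 2019 beyond
# "almost all DBD"; the cumulative tables report Sicily 10.8 (10.8/0) and
# NBench1 23.2 (23.2/0).
region,year,ud_pmp,ud_dbd_pmp,ud_dcd_pmp
Sicily,2017,15.4,15.4,0
Sicily,2018,9,9,0
Sicily,2019,8.2,8.2,0
NBench1,2017,24.4,24.4,0
NBench1,2018,24.4,24.4,0
NBench1,2019,21,21,0
IBench2,2017,19.3,11.3,8.0
IBench2,2018,17.9,12.5,5.4
IBench2,2019,18.4,11.9,6.5
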