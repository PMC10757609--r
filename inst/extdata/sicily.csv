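# Sicily regional registry, calendar years 2017-2019 (CRTS activity tables).
# ud_dbd/ud_dcd: utilized-donor counts are not published for the study years,
#   only UD/pmp rates (see ud_rates.csv); stored as NA.
# kt_dbd/kt_dcd: the per-year DBD/DCD split is not published (only the
#   2017-2019 cumulative 348 DBD / 2 DCD); both DCD transplants are assigned
#   to 2019, the first year of the regional DCD programme. All aggregate
#   results depend only on the cumulative split.
# population: not published; back-solved values live in populations.csv.
region,year,population,ud_dbd,ud_dcd,kt_dbd,kt_dcd,kt_ld,rrt_hd,rrt_pd,rrt_kt,waiting_list
Sicily,2017,NA,NA,NA,151,0,9,4328,235,543,529
Sicily,2018,NA,NA,NA,109,0,9,4199,224,633,568
Sicily,2019,NA,NA,NA,88,2,11,4183,221,722,551
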