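# IBench2 (international benchmark, Scotland), reporting years labelled
# 2017-2019. Transplant counts follow the national financial year
# (1 April 2017 - 31 March 2020) mapped onto these calendar-year labels
# without proration, as the source reports do.
region,year,population,ud_dbd,ud_dcd,kt_dbd,kt_dcd,kt_ld,rrt_hd,rrt_pd,rrt_kt,waiting_list
IBench2,2017,NA,NA,NA,128,75,84,1959,194,3024,402
IBench2,2018,NA,NA,NA,113,54,96,1942,215,3161,439
IBench2,2019,NA,NA,NA,113,69,98,1919,213,3304,409
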