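# NBench1 (national benchmark, Lazio), calendar years 2017-2019.
# The DCD programme had not started in the study period: kt_dcd = 0.
# rrt_kt (prevalent patients living with a functioning graft) is not
#   reported by the regional registry: NA.
region,year,population,ud_dbd,ud_dcd,kt_dbd,kt_dcd,kt_ld,rrt_hd,rrt_pd,rrt_kt,waiting_list
NBench1,2017,NA,NA,NA,236,0,26,4340,356,NA,922
NBench1,2018,NA,NA,NA,222,0,41,4398,334,NA,910
NBench1,2019,NA,NA,NA,181,0,42,4534,348,NA,958
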