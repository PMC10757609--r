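# National utilized-donor and kidney-transplant rates per million
# population, Italy vs United Kingdom, 2017-2019 (IRODaT). Reference data
# establishing comparability of the two national programmes.
metric,year,italy,uk
ud_pmp,2017,27.7,21.34
ud_pmp,2018,22.6,23.35
ud_pmp,2019,22.8,23.01
ud_dbd_pmp,2017,27.2,13.18
ud_dbd_pmp,2018,21.82,14.79
ud_dbd_pmp,2019,21.7,13.86
ud_dcd_pmp,2017,0.5,8.16
ud_dcd_pmp,2018,0.78,8.56
ud_dcd_pmp,2019,1.1,9.15
kt_pmp,2017,41.3,52.95
kt_pmp,2018,35.14,55.14
kt_pmp,2019,35.3,54.9
ktdd_pmp,2017,36.3,37.84
ktdd_pmp,2018,30.2,39.5
ktdd_pmp,2019,29.7,39.56
ktld_pmp,2017,5,15.11
ktld_pmp,2018,4.94,15.64
ktld_pmp,2019,5.6,15.34
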