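# Default economic parameters of the savings model.
# tariff_eur: reimbursement paid by regional commissioners per transplant
# annual_saving_eur: saving per functioning graft per year, after the first
# functioning_fraction: estimated share of transplants functioning
# lag_years: whole years before a transplant cohort starts saving
tariff_eur: 33162
annual_saving_eur: 25000
functioning_fraction: 0.80
lag_years: 1
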