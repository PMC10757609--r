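Package: ktbench
Title: Benchmarking Kidney Transplant Activity and Estimated Savings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Health-economics toolkit for regional kidney-transplant
    registries. Implements the kidney transplant coefficient of value
    (KTCoV), a lagged cohort model of estimated gross savings accrued by
    transplant activity, and benchmark comparators between regional
    programmes: per-million-population rates, waiting-list access
    fractions, donor-to-organ yield estimates, and exact tests on
    transplant typology. Ships transcribed regional activity tables for
    Sicily and two benchmark programmes, a seeded synthetic-registry
    generator, and report renderers that reproduce the study tables
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
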