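---
title: "Estimated savings from kidney transplantation: model and benchmarking methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimated savings from kidney transplantation: model and benchmarking methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktbench)
library(dplyr)
```

## The problem

Kidney transplantation (KT) is both clinically superior to dialysis for
eligible patients with end-stage kidney disease and cheaper for the health
service that pays for renal replacement therapy (RRT). Regional transplant
programmes nevertheless differ widely in activity, and a programme that
under-performs its peers forgoes real money as well as clinical benefit.
`ktbench` turns that observation into a reproducible pipeline: it models
the savings generated by a stream of transplants, and benchmarks a regional
programme's activity and savings against comparator programmes from
registry activity tables.

## The savings model

Three fixed financial/efficacy parameters drive the model
(`econ_params()`):

| parameter | symbol | default | meaning |
|---|---|---|---|
| `tariff_eur` | $T$ | 33,162 | reimbursement paid per transplant episode (EUR) |
| `annual_saving_eur` | $S$ | 25,000 | saving per *functioning* graft per year, accruing after the first post-transplant year (EUR/year) |
| `functioning_fraction` | $f$ | 0.80 | share of transplants estimated to be functioning |
| `lag_years` | $L$ | 1 | whole years before a transplant cohort starts saving |

The defaults are the published Italian governance figures the analysis was
built on. Of $n$ transplants, $fn$ are expected functioning (each saving
$S$ per year) and $(1-f)n$ non-functioning (each charged its tariff $T$).
The estimated gross saving per savings year is therefore

$$\mathrm{eGrSav}(n) \;=\; f\,n\,S - (1-f)\,n\,T \;=\; n \cdot \mathrm{KTCoV},
\qquad \mathrm{KTCoV} = f S - (1-f) T.$$

The *kidney transplant coefficient of value* (KTCoV) is the per-transplant
net saving. Because the functioning/non-functioning counts are real-valued
expectations — never rounded to whole patients — the coefficient is exactly
constant in $n$; with the defaults it is EUR 13,367.6. It can be negative
when failures are costly enough ($f < T/(S+T)$).

```{r}
compute_ktcov(econ_params())
```

Two modelling conventions deserve emphasis, because they are what make the
published savings table reproduce cell-for-cell:

* **The tariff-loss term recurs every savings year.** KTCoV is applied per
  year to the whole mature cohort, so the $(1-f)nT$ loss is charged in each
  savings year, not once at transplant. A one-off tariff loss would be
  economically arguable, but it is not the construction that the published
  accrual follows; the package adopts the recurring form.
* **No attrition beyond the functioning fraction.** Five-year graft
  survival above 80% in both source registries motivates holding $f$ fixed
  across the whole horizon; cohorts persist at full strength, so reported
  savings are a lower bound.

## The lagged accrual ledger

`build_savings_ledger()` maps activity years onto savings years. A cohort
of $n_t$ transplants in year $t$ contributes from year $t + L$ onwards, so

$$\mathrm{eGrSav}(y) \;=\; \mathrm{KTCoV} \sum_{t \,\le\, \min(y - L,\; t_{\max})} n_t,$$

with the sum over activity years in the chosen window. Savings ramp up
while cohorts mature and plateau from $t_{\max} + L$ onwards. The study
window is 2017–2019 with horizon 2022: pandemic-era activity (2020–2021)
is deliberately excluded from the window, while its savings years are kept
in the horizon.

```{r}
ledger <- build_savings_ledger(study_registry(), c(2017, 2019), 2022)
ledger_table(ledger)
```

An independent brute-force oracle (cohort-by-cohort accumulation) is kept
in the test suite and must agree with this closed form to within 1e-6 EUR
on a thousand randomly drawn registries; arithmetic is plain double
precision, which at the EUR-1e7 scale leaves ~1e-9 EUR of headroom, and
comparisons to published one-decimal values are made at 0.1 EUR.

## Benchmark comparators

* `pmp_rate()` — annualised events per million population,
  $(c/\text{years})/(\text{pop}/10^6)$. The source tables never print
  populations; `region_populations()` ships values back-solved from
  published rates (documented in the file) so the published rates
  round-trip. They are analysis conventions, not census figures.
* `waiting_list_fraction()` — the waiting list as a percentage of the
  combined HD+PD dialysis population; reported at integer precision for
  the study region (12%) and one decimal for benchmarks (19.5%), the two
  conventions used in the source report.
* `typology_test()` / `fisher_exact_2x2()` — deceased-donor (DBD+DCD)
  versus living-donor transplant counts for two regions, tested with the
  two-sided Fisher exact test under the standard minimum-likelihood rule
  (`stats::fisher.test` performs the enumeration; a hand-written
  hypergeometric oracle in the test suite agrees with it exhaustively on
  all 2×2 tables with total $N \le 40$, enumerated over canonical
  representatives of the row/column-swap symmetry). The sidedness of the
  published test is not stated; the two-sided convention reproduces the
  published 0.0007 at four decimals. P-values below $10^{-4}$ are rendered
  `"<0.0001"`, the reporting floor the published table uses.
* `organ_yield_estimate()` — the study setting's yield conventions: each
  utilized donor (UD) generates on average three transplantable organs,
  and five UD lead to eight kidney transplants. For a deficit of 66 UD the
  exact kidney figure is $66 \times 8/5 = 105.6$; the package reports the
  exact value and its floor (105) as the "at least" bound.

### Rounding

Published tables mix rounding conventions; the package uses
half-away-from-zero (`round_half_away()`) everywhere, at one decimal for
percentages and rates. A handful of published cells cannot be reproduced
under any single convention (e.g. a typology percentage printed 0.6 where
the ratio is 0.53, a waiting-list average printed 550 where the yearly
snapshots average 549.33); the package reports the consistently computed
values, and all headline results are unaffected.

### Data-model choices

The registry schema models counts that the sources leave unreported as
explicit NA: NBench1's transplant-prevalence series, and utilized-donor
*counts* for all regions (only UD/pmp rates were ever published — bundled
as `ud_rate_reference()`). NA snapshots are excluded from period averages.
The per-year DBD/DCD split of the study region is also unpublished (only
the cumulative 348/2); the bundled fixture assigns both DCD transplants to
2019, the first year of the regional DCD programme — every aggregate
result depends only on the cumulative split. Scotland's financial-year
reporting (April–March) is mapped onto calendar-year labels without
proration, exactly as the source does.

## The synthetic registry generator

`generate_registry()` exists so every pipeline stage can be exercised, at
scale, with known ground truth. Per region-year it draws the
transplant total from a Poisson distribution with mean
$\text{baseline} \times \text{trend}^{y - y_0}$ (negative binomial with
variance/mean = `dispersion` when overdispersion is wanted), splits it
DBD/DCD/LD by a multinomial draw from `typology_mix`, draws the dialysis
population Poisson around `dialysis_base` (split 95/5 HD/PD), the waiting
list binomial at `wl_fraction` of the dialysis population, and utilized
donors Poisson at 5 donors per 8 deceased-donor transplants. Defaults
(~150 KT/region-year, ~4,500 dialysis patients, 15% waiting-list share)
are the scale of the regional programmes analysed. Generation is fully
determined by the config's seed and never touches the global RNG stream.

What it deliberately does **not** emulate: waiting-list queueing dynamics,
donor-consent pipelines, organ allocation, correlation between donor
activity and transplant counts beyond the mean yield, or year-to-year
autocorrelation. Passing the property suite therefore shows the arithmetic
pipeline is correct on registries with the right *shape and scale*, not
that the noise model matches any real registry.

Parameter recovery is part of the acceptance suite at sizes chosen to be
decisive yet quick: typology-mix recovery within three standard errors on
10,000 region-years (~1 million transplants), trend recovery on 50
regions × 3 years, and the accrual-oracle comparison on 1,000 registries.

## Known limitations

* No discounting, inflation adjustment, or QALY modelling; the underlying
  cost figures are themselves a decade old, and the model is explicit that
  reuse elsewhere requires re-validated tariffs and savings
  (`sensitivity_grid()` exposes how KTCoV moves with all three
  parameters — monotone up in $S$ and $f$, down in $T$).
* Societal costs (travel, productivity) are out of scope; the only
  out-of-region quantity modelled is the tariff product
  (`out_of_region_cost()`), a lower bound on the true cost.
* Savings differences between programmes are reported, never tested
  statistically — small financial differences can matter to commissioners
  regardless of significance, and the source analysis makes the same
  choice.
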