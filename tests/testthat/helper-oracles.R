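# Independent oracles, kept free of the package's own code paths.

# Brute-force cohort accrual: each activity-year cohort of n_t transplants
# contributes f*n_t*S - (1-f)*n_t*T in every savings year y >= t + lag,
# up to the horizon. Summing cohort-by-cohort must equal the closed-form
# ledger (KTCoV times mature transplant count).
oracle_cohort_savings <- function(kt_by_year, window, horizon_end, params) {
  years <- seq(window[1], window[2])
  stopifnot(length(kt_by_year) == length(years))
  savings_years <- seq(window[1] + params$lag_years, horizon_end)
  f <- params$functioning_fraction
  s <- params$annual_saving_eur
  tr <- params$tariff_eur
  egrsav <- vapply(savings_years, function(y) {
    total <- 0
    for (i in seq_along(years)) {
      if (years[i] + params$lag_years <= y) {
        total <- total + f * kt_by_year[i] * s - (1 - f) * kt_by_year[i] * tr
      }
    }
    total
  }, double(1))
  data.frame(year = savings_years, egrsav = egrsav)
}

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins (minimum-likelihood rule). Independent of
# stats::fisher.test.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  x <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- dhyper(x, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Tiny hand-built registry helper for tests.
make_registry <- function(region = "R1", years = 2017:2019,
                          kt_dbd = c(10, 10, 10), kt_dcd = 0, kt_ld = 0,
                          rrt_hd = 100, rrt_pd = 10, waiting_list = 20) {
  as_registry(tibble::tibble(
    region = region, year = years, population = NA_real_,
    ud_dbd = NA_real_, ud_dcd = NA_real_,
    kt_dbd = kt_dbd, kt_dcd = kt_dcd, kt_ld = kt_ld,
    rrt_hd = rrt_hd, rrt_pd = rrt_pd, rrt_kt = NA_real_,
    waiting_list = waiting_list
  ))
}
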