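paper_params <- econ_params()

test_that("the coefficient of value matches its closed form", {
  expect_equal(compute_ktcov(paper_params), 13367.6)
  expect_equal(compute_ktcov(econ_params(functioning_fraction = 1)), 25000)
  expect_equal(compute_ktcov(econ_params(functioning_fraction = 0)), -33162)
  expect_equal(
    compute_ktcov(econ_params(25000, 25000, 0.5)), 0
  )
})

test_that("gross savings scale linearly in the transplant count", {
  expect_equal(egrs_from_count(101), 1350127.6)
  expect_equal(egrs_from_count(0), 0)
  # cross-check against the expanded expectation form
  expect_equal(egrs_from_count(150), 0.8 * 150 * 25000 - 0.2 * 150 * 33162)
  expect_equal(egrs_from_count(150), 2005140)
  expect_error(egrs_from_count(-1), class = "ktbench_domain_error")

  withr::with_seed(7, {
    n <- sample(1:500, 25)
    # per-transplant value is constant in n
    expect_equal(egrs_from_count(n) / n, rep(13367.6, 25))
    a <- sample(0:300, 25)
    b <- sample(0:300, 25)
    expect_equal(egrs_from_count(a + b), egrs_from_count(a) + egrs_from_count(b))
  })
})

test_that("the savings ledger reproduces the published accrual", {
  reg <- study_registry()
  led <- build_savings_ledger(reg, c(2017, 2019), 2022, paper_params)
  cell <- function(r, y) led$egrsav[led$region == r & led$year == y]

  expect_equal(cell("Sicily", 2018), 2138816, tolerance = 0.1 / 2138816)
  expect_equal(cell("Sicily", 2019), 3716192.8)
  expect_equal(cell("Sicily", 2020), 5066320.4)
  expect_equal(cell("Sicily", 2021), 5066320.4)
  expect_equal(cell("Sicily", 2022), 5066320.4)
  expect_equal(cell("NBench1", 2018), 3502311.2)
  expect_equal(cell("NBench1", 2020), 9998964.8)
  expect_equal(cell("IBench2", 2018), 3836501.2)
  expect_equal(cell("IBench2", 2020), 11095108)
  expect_equal(cell("IBench2", 2022), 11095108)
})

test_that("cumulative and foregone savings match the published comparison", {
  led <- build_savings_ledger(study_registry(), c(2017, 2019), 2022)
  cum <- cumulative_savings(led)
  get <- function(r) cum$cumulative_egrsav[cum$region == r]
  expect_equal(get("Sicily"), 21053970)
  expect_equal(get("NBench1"), 40517195.6)
  expect_equal(get("IBench2"), 44474005.2)

  fs_nb <- foregone_savings(ledger_region(led, "Sicily"), ledger_region(led, "NBench1"))
  expect_equal(fs_nb$cumulative, 40517195.6 - 21053970)
  expect_equal(fs_nb$cumulative, 19463225.6)
  fs_ib <- foregone_savings(ledger_region(led, "Sicily"), ledger_region(led, "IBench2"))
  expect_equal(fs_ib$cumulative, 23420035.2)
  expect_equal(sum(fs_ib$per_year$difference), fs_ib$cumulative)

  same <- foregone_savings(ledger_region(led, "Sicily"), ledger_region(led, "Sicily"))
  expect_equal(same$cumulative, 0)
  expect_true(all(same$per_year$difference == 0))

  short <- build_savings_ledger(study_registry(), c(2017, 2019), 2020)
  expect_error(
    foregone_savings(ledger_region(led, "Sicily"), ledger_region(short, "NBench1")),
    class = "ktbench_alignment_error"
  )
})

test_that("degenerate ledgers behave: zero activity and early horizons", {
  zero <- make_registry(kt_dbd = c(0, 0, 0))
  led <- build_savings_ledger(zero, c(2017, 2019), 2022)
  expect_true(all(led$egrsav == 0))
  expect_equal(cumulative_savings(led)$cumulative_egrsav, 0)

  expect_warning(
    empty <- build_savings_ledger(make_registry(), c(2017, 2019), 2017),
    "matures"
  )
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(cumulative_savings(empty)), 0)
})

test_that("out-of-region transplants cost the tariff per patient", {
  expect_equal(out_of_region_cost(71, 33162), 2354502)
  expect_equal(out_of_region_cost(71), 2354502)
  expect_equal(out_of_region_cost(0, 99999), 0)
  expect_equal(out_of_region_cost(10, 40000), 400000)
})

test_that("sensitivity grid is exhaustive and monotone", {
  grid <- sensitivity_grid(
    tariff_range = c(25000, 33162, 40000),
    saving_range = c(20000, 25000, 30000),
    fraction_range = c(0.5, 0.8, 1.0)
  )
  expect_equal(nrow(grid), 27)
  base_cell <- dplyr::filter(grid, tariff_eur == 33162,
                             annual_saving_eur == 25000,
                             functioning_fraction == 0.8)
  expect_equal(base_cell$ktcov_eur, 13367.6)
  expect_equal(
    dplyr::filter(grid, functioning_fraction == 1)$ktcov_eur,
    dplyr::filter(grid, functioning_fraction == 1)$annual_saving_eur
  )
  expect_equal(
    dplyr::filter(grid, tariff_eur == 25000, annual_saving_eur == 25000,
                  functioning_fraction == 0.5)$ktcov_eur,
    0
  )
  mono <- grid |> dplyr::arrange(tariff_eur, annual_saving_eur, functioning_fraction)
  # increasing in f within fixed (T, S); decreasing in T within fixed (S, f)
  by_ts <- split(mono$ktcov_eur, paste(mono$tariff_eur, mono$annual_saving_eur))
  expect_true(all(vapply(by_ts, function(v) all(diff(v) >= 0), logical(1))))
  by_sf <- split(grid$ktcov_eur[order(grid$tariff_eur)],
                 paste(grid$annual_saving_eur, grid$functioning_fraction)[order(grid$tariff_eur)])
  expect_true(all(vapply(by_sf, function(v) all(diff(v) <= 0), logical(1))))
})

test_that("closed-form ledger equals the brute-force cohort simulator", {
  # fixed study registry first
  reg <- study_registry()
  led <- build_savings_ledger(reg, c(2017, 2019), 2022)
  for (r in unique(reg$region)) {
    kt <- dplyr::filter(reg, region == r)$kt_total
    oracle <- oracle_cohort_savings(kt, c(2017, 2019), 2022, paper_params)
    expect_equal(led$egrsav[led$region == r], oracle$egrsav, tolerance = 1e-9)
  }

  # random activity patterns, lags and horizons
  withr::with_seed(11, {
    for (i in 1:50) {
      n_years <- sample(1:6, 1)
      years <- 2000 + seq_len(n_years)
      kt <- sample(0:400, n_years, replace = TRUE)
      lag <- sample(0:2, 1)
      pars <- econ_params(
        tariff_eur = runif(1, 0, 60000),
        annual_saving_eur = runif(1, 0, 60000),
        functioning_fraction = runif(1),
        lag_years = lag
      )
      horizon <- max(years) + sample(0:4, 1)
      if (horizon < years[1] + lag) next
      reg_i <- make_registry(years = years, kt_dbd = kt)
      led_i <- build_savings_ledger(reg_i, range(years), horizon, pars)
      oracle <- oracle_cohort_savings(kt, range(years), horizon, pars)
      expect_equal(led_i$egrsav, oracle$egrsav, tolerance = 1e-6)
    }
  })
})

test_that("savings are non-decreasing and plateau once cohorts mature", {
  withr::with_seed(3, {
    for (i in 1:20) {
      reg <- generate_registry(synthetic_config(
        regions = tibble::tibble(region = "A", population = 5e6),
        years = c(2015, 2019), baseline_kt = sample(50:300, 1),
        annual_trend = runif(1, 0.7, 1.3), seed = i
      ))
      led <- build_savings_ledger(reg, c(2015, 2019), 2024)
      expect_true(all(diff(led$egrsav) >= 0))
      plateau <- led$egrsav[led$year > 2019 + 1]
      expect_equal(plateau, rep(plateau[1], length(plateau)))
      expect_equal(plateau[1], egrs_from_count(sum(reg$kt_total)))
    }
  })
})

test_that("economic parameters reject invalid values and read from YAML", {
  expect_error(econ_params(functioning_fraction = 1.2))
  expect_error(econ_params(tariff_eur = -1))
  expect_error(econ_params(lag_years = 0.5))

  expect_equal(read_econ_params(), paper_params)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("tariff_eur: 40000", "functioning_fraction: 0.9"), path)
  custom <- read_econ_params(path)
  expect_equal(custom$tariff_eur, 40000)
  expect_equal(custom$functioning_fraction, 0.9)
  expect_equal(custom$annual_saving_eur, 25000)
})
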