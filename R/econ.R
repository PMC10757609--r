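#' Economic parameters of the transplant savings model
#'
#' Bundles the fixed financial parameters the model combines with yearly
#' transplant counts: the reimbursement tariff paid per transplant, the
#' yearly saving generated by each functioning graft (accruing after the
#' first post-transplant year), the fraction of transplants estimated to
#' be functioning, and the accrual lag in whole years.
#'
#' Defaults are the study values: tariff EUR 33,162, saving EUR 25,000
#' per functioning graft per year, 80% functioning, one-year lag.
#'
#' @param tariff_eur reimbursement per transplant, EUR (>= 0).
#' @param annual_saving_eur saving per functioning graft per year, EUR
#'   (>= 0).
#' @param functioning_fraction fraction of transplants functioning, in
#'   `[0, 1]`.
#' @param lag_years whole years before a transplant cohort starts saving
#'   (>= 0).
#' @return an object of class `econ_params`.
#' @examples
#' econ_params()
#' econ_params(functioning_fraction = 0.85)
#' @export
econ_params <- function(tariff_eur = 33162,
                        annual_saving_eur = 25000,
                        functioning_fraction = 0.80,
                        lag_years = 1L) {
  stopifnot(
    length(tariff_eur) == 1, is.finite(tariff_eur), tariff_eur >= 0,
    length(annual_saving_eur) == 1, is.finite(annual_saving_eur),
    annual_saving_eur >= 0,
    length(functioning_fraction) == 1, is.finite(functioning_fraction),
    functioning_fraction >= 0, functioning_fraction <= 1,
    length(lag_years) == 1, is.finite(lag_years), lag_years >= 0,
    lag_years == floor(lag_years)
  )
  structure(
    list(
      tariff_eur = as.numeric(tariff_eur),
      annual_saving_eur = as.numeric(annual_saving_eur),
      functioning_fraction = as.numeric(functioning_fraction),
      lag_years = as.integer(lag_years)
    ),
    class = "econ_params"
  )
}

#' @export
print.econ_params <- function(x, ...) {
  cat("Transplant savings model parameters\n")
  cat(sprintf("  tariff per KT:            EUR %s\n", format_eur(x$tariff_eur)))
  cat(sprintf("  saving per functioning KT: EUR %s / year\n",
              format_eur(x$annual_saving_eur)))
  cat(sprintf("  functioning fraction:      %.0f%%\n", 100 * x$functioning_fraction))
  cat(sprintf("  accrual lag:               %d year(s)\n", x$lag_years))
  cat(sprintf("  KTCoV:                     EUR %s per KT\n",
              format_eur(compute_ktcov(x))))
  invisible(x)
}

#' Read economic parameters from a YAML config
#'
#' @param path YAML file with keys `tariff_eur`, `annual_saving_eur`,
#'   `functioning_fraction`, `lag_years`; absent keys fall back to the
#'   study defaults.
#' @return an `econ_params` object.
#' @export
read_econ_params <- function(path = NULL) {
  path <- path %||% ktb_extdata("econ_params.yaml")
  cfg <- yaml::read_yaml(path)
  defaults <- econ_params()
  econ_params(
    tariff_eur = cfg$tariff_eur %||% defaults$tariff_eur,
    annual_saving_eur = cfg$annual_saving_eur %||% defaults$annual_saving_eur,
    functioning_fraction = cfg$functioning_fraction %||% defaults$functioning_fraction,
    lag_years = cfg$lag_years %||% defaults$lag_years
  )
}

#' Kidney transplant coefficient of value (KTCoV)
#'
#' The net estimated saving per transplant and savings year:
#' \deqn{KTCoV = f S - (1 - f) T}
#' where \eqn{f} is the functioning fraction, \eqn{S} the yearly saving
#' per functioning graft and \eqn{T} the tariff charged for a failed
#' graft. Because the functioning and non-functioning counts are the
#' expectations \eqn{f n} and \eqn{(1-f) n}, the coefficient does not
#' depend on the number of transplants \eqn{n}; gross savings are simply
#' \eqn{n \times KTCoV}. The value may be negative when failures are
#' costly enough.
#'
#' @param params an [econ_params()] object.
#' @return net saving per transplant per savings year, EUR.
#' @examples
#' compute_ktcov(econ_params())  # 13367.6 with the study parameters
#' @export
compute_ktcov <- function(params = econ_params()) {
  stopifnot(inherits(params, "econ_params"))
  params$functioning_fraction * params$annual_saving_eur -
    (1 - params$functioning_fraction) * params$tariff_eur
}

#' Estimated gross savings from a transplant count
#'
#' Expected net saving generated in one savings year by `n_kt`
#' transplants: `n_kt * compute_ktcov(params)`. The functioning and
#' failed counts are real-valued expectations (`f * n`, `(1 - f) * n`),
#' never rounded to whole patients — this is what makes the per-transplant
#' coefficient exactly constant in `n`.
#'
#' @param n_kt number of transplants (>= 0; vectorised).
#' @inheritParams compute_ktcov
#' @return EUR, same length as `n_kt`.
#' @examples
#' egrs_from_count(101)  # lowest study year
#' @export
egrs_from_count <- function(n_kt, params = econ_params()) {
  if (any(!is.finite(n_kt) | n_kt < 0)) {
    abort("n_kt must be non-negative", class = "ktbench_domain_error")
  }
  n_kt * compute_ktcov(params)
}

#' Build the lagged savings ledger for each region
#'
#' Maps transplant activity in `window` onto estimated gross savings per
#' calendar year. A cohort transplanted in year *t* starts saving in year
#' *t + lag* and persists at full strength through the horizon (no
#' attrition beyond the functioning fraction already inside the
#' coefficient), so
#' \deqn{eGrSav(y) = KTCoV \sum_{t \le \min(y - lag,\; t_{max})} n_t}
#' with the sum over activity years in the window. Savings plateau once
#' every cohort has matured.
#'
#' @param registry registry tibble (one or more regions).
#' @param window `c(first, last)` activity years; must lie inside each
#'   region's recorded years.
#' @param horizon_end last savings year of the ledger.
#' @inheritParams compute_ktcov
#' @return a `savings_ledger`: a tibble with columns `region`, `year`,
#'   `kt_mature` (transplants accrued by that savings year) and `egrsav`
#'   (EUR), carrying the parameters, window and horizon as attributes.
#'   If no cohort matures by `horizon_end` the ledger is empty, with a
#'   warning.
#' @examples
#' build_savings_ledger(study_registry(), c(2017, 2019), 2022)
#' @export
build_savings_ledger <- function(registry, window = range(registry$year),
                                 horizon_end = max(window) + 3,
                                 params = econ_params()) {
  stopifnot(inherits(params, "econ_params"), length(window) == 2)
  window <- as.integer(window)
  activity_years <- seq(window[1], window[2])
  ktcov <- compute_ktcov(params)
  first_savings_year <- window[1] + params$lag_years

  if (horizon_end < first_savings_year) {
    warn("horizon ends before any transplant cohort matures; empty ledger")
    out <- tibble::tibble(
      region = character(), year = integer(),
      kt_mature = integer(), egrsav = double()
    )
    return(new_savings_ledger(out, params, window, horizon_end))
  }

  act <- registry |> dplyr::filter(.data$year %in% activity_years)
  for (reg in unique(registry$region)) {
    have <- act$year[act$region == reg]
    if (!all(activity_years %in% have)) {
      abort(
        sprintf("activity window %d-%d not fully recorded for region %s",
                window[1], window[2], reg),
        class = "ktbench_range_error"
      )
    }
  }
  savings_years <- seq(first_savings_year, horizon_end)
  out <- act |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(function(d, key) {
      kt_mature <- vapply(savings_years, function(y) {
        sum(d$kt_total[d$year <= min(y - params$lag_years, window[2])])
      }, double(1))
      tibble::tibble(
        year = savings_years,
        kt_mature = as.integer(kt_mature),
        egrsav = kt_mature * ktcov
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$region, unique(registry$region)), .data$year)
  new_savings_ledger(out, params, window, horizon_end)
}

new_savings_ledger <- function(df, params, window, horizon_end) {
  structure(
    df,
    params = params, window = window, horizon_end = as.integer(horizon_end),
    class = c("savings_ledger", class(tibble::tibble()))
  )
}

#' @export
print.savings_ledger <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf(
    "Savings ledger: activity %d-%d, horizon %d, KTCoV EUR %s/KT\n",
    w[1], w[2], attr(x, "horizon_end"),
    format_eur(compute_ktcov(attr(x, "params")))
  ))
  NextMethod()
}

#' Cumulative estimated gross savings per region
#'
#' @param ledger a `savings_ledger` from [build_savings_ledger()].
#' @return tibble with columns `region` and `cumulative_egrsav` (EUR,
#'   the sum of the per-year ledger values); zero rows sum to zero.
#' @examples
#' study_registry() |>
#'   build_savings_ledger(c(2017, 2019), 2022) |>
#'   cumulative_savings()
#' @export
cumulative_savings <- function(ledger) {
  tibble::as_tibble(ledger) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(cumulative_egrsav = sum(.data$egrsav), .groups = "drop")
}

#' Foregone savings of one programme against a benchmark
#'
#' Compares two single-region ledgers over the same savings years: the
#' cumulative shortfall `sum(benchmark) - sum(program)` and the year-wise
#' difference series. A positive value is money the programme's health
#' service did not save relative to the benchmark.
#'
#' @param ledger_a ledger of the programme under study (single region).
#' @param ledger_b ledger of the benchmark programme (single region).
#' @return list with `cumulative` (EUR scalar) and `per_year`, a tibble
#'   with columns `year`, `egrsav_a`, `egrsav_b`, `difference`.
#' @export
foregone_savings <- function(ledger_a, ledger_b) {
  a <- tibble::as_tibble(ledger_a)
  b <- tibble::as_tibble(ledger_b)
  stopifnot(
    dplyr::n_distinct(a$region) <= 1,
    dplyr::n_distinct(b$region) <= 1
  )
  if (!identical(sort(a$year), sort(b$year))) {
    abort("ledgers cover different savings years and cannot be compared",
          class = "ktbench_alignment_error")
  }
  per_year <- dplyr::inner_join(
    dplyr::select(a, "year", egrsav_a = "egrsav"),
    dplyr::select(b, "year", egrsav_b = "egrsav"),
    by = "year"
  ) |>
    dplyr::mutate(difference = .data$egrsav_b - .data$egrsav_a) |>
    dplyr::arrange(.data$year)
  list(cumulative = sum(per_year$difference), per_year = per_year)
}

#' Tariff cost of patients transplanted outside the region
#'
#' Patients transplanted out of region are reimbursed at the provider
#' tariff; this is the minimum expected cost of that cohort (out-of-region
#' providers may charge more, and travel costs fall on patients).
#'
#' @param n_patients number of patients transplanted out of region.
#' @param tariff_eur tariff per transplant, EUR.
#' @return EUR.
#' @examples
#' out_of_region_cost(71)
#' @export
out_of_region_cost <- function(n_patients, tariff_eur = econ_params()$tariff_eur) {
  stopifnot(n_patients >= 0, tariff_eur >= 0)
  n_patients * tariff_eur
}

#' Sensitivity of the coefficient of value to its parameters
#'
#' Evaluates [compute_ktcov()] over the full grid of tariff, saving and
#' functioning-fraction values, for reuse of the model in settings with
#' different reimbursement and dialysis costs. The coefficient is
#' increasing in the saving and the functioning fraction and decreasing
#' in the tariff.
#'
#' @param base [econ_params()] supplying the lag (and any range given as
#'   `NULL` collapses to the base value).
#' @param tariff_range,saving_range,fraction_range numeric vectors of
#'   parameter values to cross.
#' @return tibble with columns `tariff_eur`, `annual_saving_eur`,
#'   `functioning_fraction`, `ktcov_eur`, one row per grid cell.
#' @examples
#' sensitivity_grid(fraction_range = c(0.7, 0.8, 0.9))
#' @export
sensitivity_grid <- function(base = econ_params(),
                             tariff_range = NULL,
                             saving_range = NULL,
                             fraction_range = NULL) {
  grid <- tidyr::expand_grid(
    tariff_eur = tariff_range %||% base$tariff_eur,
    annual_saving_eur = saving_range %||% base$annual_saving_eur,
    functioning_fraction = fraction_range %||% base$functioning_fraction
  )
  stopifnot(nrow(grid) > 0)
  grid |>
    dplyr::mutate(
      ktcov_eur = purrr::pmap_dbl(
        list(.data$tariff_eur, .data$annual_saving_eur, .data$functioning_fraction),
        function(t, s, f) {
          compute_ktcov(econ_params(t, s, f, base$lag_years))
        }
      )
    )
}
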