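#' Full benchmark report for a registry
#'
#' Runs the whole pipeline on a registry: period activity summary (with
#' per-million rates and waiting-list access fractions when populations
#' are supplied), the deceased- vs living-donor typology comparison, the
#' per-year savings ledger and the cumulative and foregone savings of
#' every region against the reference.
#'
#' @param registry registry tibble from [load_registry()] or
#'   [study_registry()].
#' @param window `c(first, last)` activity years.
#' @param horizon_end last savings year.
#' @param params an [econ_params()].
#' @param populations tibble with columns `region`, `population`, or
#'   `NULL`; when absent the per-million columns are omitted (other
#'   tables are still produced).
#' @param reference region against which typology and foregone savings
#'   are computed; defaults to the first region.
#' @return a `ktbench_report` list with elements `activity`, `typology`,
#'   `ledger` (the [build_savings_ledger()] object), `ledger_table`
#'   (years x regions with a cumulative row), `foregone`, `params`.
#' @examples
#' rep <- benchmark_report(study_registry(), c(2017, 2019), 2022,
#'                         populations = region_populations())
#' rep$ledger_table
#' @export
benchmark_report <- function(registry, window = range(registry$year),
                             horizon_end = max(window) + 3,
                             params = econ_params(),
                             populations = NULL,
                             reference = NULL) {
  summary <- aggregate_period(registry, window)
  reference <- reference %||% registry$region[1]
  n_years <- max(window) - min(window) + 1

  activity <- summary |>
    dplyr::mutate(
      wl_fraction_pct = waiting_list_fraction(
        .data$avg_waiting_list, .data$avg_hd, .data$avg_pd
      )
    )
  if (!is.null(populations)) {
    activity <- activity |>
      dplyr::left_join(populations, by = "region") |>
      dplyr::mutate(
        ktdd_pmp = pmp_rate(.data$ktdd, .data$population, n_years),
        ktld_pmp = pmp_rate(.data$kt_ld, .data$population, n_years),
        kt_pmp = pmp_rate(.data$kt_total, .data$population, n_years)
      )
  }

  ledger <- build_savings_ledger(registry, window, horizon_end, params)
  cum <- cumulative_savings(ledger)
  foregone <- purrr::map_dfr(
    setdiff(summary$region, reference),
    function(reg) {
      fs <- foregone_savings(
        ledger_region(ledger, reference), ledger_region(ledger, reg)
      )
      tibble::tibble(
        reference = reference, benchmark = reg,
        foregone_eur = fs$cumulative
      )
    }
  )

  structure(
    list(
      activity = activity,
      typology = typology_test(summary, reference),
      ledger = ledger,
      ledger_table = ledger_table(ledger),
      cumulative = cum,
      foregone = foregone,
      params = params,
      window = as.integer(window),
      horizon_end = as.integer(horizon_end),
      reference = reference
    ),
    class = "ktbench_report"
  )
}

#' Extract one region's rows from a savings ledger
#'
#' @param ledger a `savings_ledger`.
#' @param region region identifier.
#' @return single-region `savings_ledger`.
#' @export
ledger_region <- function(ledger, region) {
  stopifnot(region %in% ledger$region)
  out <- tibble::as_tibble(ledger)[ledger$region == region, , drop = FALSE]
  new_savings_ledger(out, attr(ledger, "params"), attr(ledger, "window"),
                     attr(ledger, "horizon_end"))
}

#' Savings ledger in report layout
#'
#' Pivots a ledger to one row per savings year and one column per region,
#' appending a cumulative row — the layout of the published savings
#' comparison.
#'
#' @param ledger a `savings_ledger`.
#' @param eu_format if `TRUE`, cells are continental-format strings
#'   (`"5.066.320,4"`); otherwise numeric EUR.
#' @return tibble with a `year` character column followed by one column
#'   per region.
#' @export
ledger_table <- function(ledger, eu_format = FALSE) {
  wide <- tibble::as_tibble(ledger) |>
    dplyr::select("region", "year", "egrsav") |>
    tidyr::pivot_wider(names_from = "region", values_from = "egrsav") |>
    dplyr::mutate(year = as.character(.data$year))
  cum <- cumulative_savings(ledger)
  total <- tibble::as_tibble(
    c(list(year = "cumulative"),
      setNames(as.list(cum$cumulative_egrsav), cum$region))
  )
  out <- dplyr::bind_rows(wide, total[names(wide)])
  if (eu_format) {
    out <- dplyr::mutate(out, dplyr::across(-"year", \(x) format_eur(x, eu_format = TRUE)))
  }
  out
}

#' @export
print.ktbench_report <- function(x, ...) {
  cat(sprintf("Benchmark report: activity %d-%d, savings horizon %d\n",
              x$window[1], x$window[2], x$horizon_end))
  cat(sprintf("KTCoV: EUR %s per transplant\n\n", format_eur(compute_ktcov(x$params))))
  cat("Activity summary:\n")
  print(x$activity)
  cat("\nTransplant typology vs", x$reference, "(Fisher exact):\n")
  print(x$typology)
  cat("\nEstimated gross savings (EUR):\n")
  print(x$ledger_table)
  if (nrow(x$foregone) > 0) {
    cat("\nForegone savings vs benchmarks (EUR):\n")
    print(x$foregone)
  }
  invisible(x)
}

#' Write a benchmark report to delimited files
#'
#' Emits `activity.csv`, `typology.csv`, `ledger.csv` (report layout) and
#' `foregone.csv` under `dir`.
#'
#' @param report a `ktbench_report`.
#' @param dir output directory, created if needed.
#' @param eu_format write ledger cells in continental number format.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, eu_format = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$activity, file.path(dir, "activity.csv"), na = "NA")
  readr::write_csv(report$typology, file.path(dir, "typology.csv"), na = "NA")
  readr::write_csv(ledger_table(report$ledger, eu_format = eu_format),
                   file.path(dir, "ledger.csv"), na = "NA")
  readr::write_csv(report$foregone, file.path(dir, "foregone.csv"), na = "NA")
  invisible(dir)
}

#' Generate a synthetic registry and report on it
#'
#' What-if runs: draws a registry from [generate_registry()] and pushes
#' it through [benchmark_report()] with the given economic parameters.
#' Identical configurations yield identical reports.
#'
#' @param config a [synthetic_config()].
#' @param params an [econ_params()].
#' @param horizon_end last savings year; defaults to three years past the
#'   activity window, the study convention.
#' @return list with `registry` and `report`.
#' @export
simulate_report <- function(config, params = econ_params(),
                            horizon_end = config$years[2] + 3) {
  registry <- generate_registry(config)
  report <- benchmark_report(
    registry, window = config$years, horizon_end = horizon_end,
    params = params,
    populations = dplyr::select(config$regions, "region", "population")
  )
  list(registry = registry, report = report)
}
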