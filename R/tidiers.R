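#' Tidy a savings ledger
#'
#' One row per region and savings year, with the mature transplant count
#' and the estimated gross savings.
#'
#' @param x a `savings_ledger`.
#' @param ... unused.
#' @return tibble with columns `region`, `year`, `kt_mature`, `egrsav`.
#' @export
tidy.savings_ledger <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row-per-region summary of a savings ledger
#'
#' @param x a `savings_ledger`.
#' @param ... unused.
#' @return tibble with columns `region`, `years` (number of savings
#'   years), `first_year`, `last_year`, `ktcov_eur`, `plateau_egrsav`
#'   (savings in the final, fully matured year) and `cumulative_egrsav`.
#' @export
glance.savings_ledger <- function(x, ...) {
  ktcov <- compute_ktcov(attr(x, "params"))
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      years = dplyr::n(),
      first_year = min(.data$year),
      last_year = max(.data$year),
      ktcov_eur = ktcov,
      plateau_egrsav = .data$egrsav[which.max(.data$year)],
      cumulative_egrsav = sum(.data$egrsav),
      .groups = "drop"
    )
}

#' Plot the savings accrual of each region
#'
#' Step-and-point plot of estimated gross savings per savings year, one
#' colour per region: the ramp while cohorts mature, then the plateau.
#'
#' @param object a `savings_ledger`.
#' @param ... unused.
#' @return a ggplot object.
#' @examples
#' ledger <- build_savings_ledger(study_registry(), c(2017, 2019), 2022)
#' autoplot(ledger)
#' @export
autoplot.savings_ledger <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$egrsav / 1e6,
                                   colour = .data$region)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = unique(df$year)) +
    ggplot2::labs(
      x = "savings year",
      y = "estimated gross savings (EUR millions)",
      colour = "region",
      title = "Lagged savings accrual from transplant activity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot transplant activity by typology
#'
#' Stacked per-year bars of DBD, DCD and living-donor transplants,
#' facetted by region.
#'
#' @param registry registry tibble.
#' @return a ggplot object.
#' @examples
#' plot_activity(study_registry())
#' @export
plot_activity <- function(registry) {
  df <- registry |>
    dplyr::select("region", "year", dbd = "kt_dbd", dcd = "kt_dcd",
                  living = "kt_ld") |>
    tidyr::pivot_longer(c("dbd", "dcd", "living"),
                        names_to = "typology", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$count,
                                   fill = .data$typology)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$region)) +
    ggplot2::scale_x_continuous(breaks = unique(df$year)) +
    ggplot2::labs(x = NULL, y = "kidney transplants", fill = "typology",
                  title = "Transplant activity by donor typology") +
    ggplot2::theme_minimal()
}
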