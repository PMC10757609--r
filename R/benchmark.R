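#' Annualised rate per million population
#'
#' `(count / n_years) / (population / 1e6)`, the standard comparator for
#' donation and transplant activity across territories of different size.
#'
#' @param count number of events over the period (vectorised).
#' @param population persons; must be known and strictly positive.
#' @param n_years length of the period in years (>= 1).
#' @param digits decimal places in the reported rate (half-away rounding);
#'   `NULL` for the unrounded value.
#' @return events per million population per year.
#' @examples
#' pmp_rate(348, 4915254, 3)  # Sicily deceased-donor KT rate, 23.6
#' @export
pmp_rate <- function(count, population, n_years = 1, digits = 1) {
  if (any(is.na(population))) {
    abort("population required to compute a per-million rate",
          class = "ktbench_population_error")
  }
  stopifnot(all(population > 0), n_years >= 1, all(count >= 0))
  rate <- (count / n_years) / (population / 1e6)
  if (is.null(digits)) rate else round_half_away(rate, digits)
}

#' Waiting-list access fraction
#'
#' Share of the combined dialysis population (haemodialysis + peritoneal
#' dialysis) active on the deceased-donor transplant waiting list:
#' `100 * wl / (hd + pd)`. A low fraction flags restricted access to
#' transplantation rather than low need.
#'
#' @param avg_wl average waiting-list size over the period.
#' @param avg_hd,avg_pd average prevalent haemodialysis / peritoneal
#'   dialysis patients; their sum must be positive.
#' @param digits decimal places (0 and 1 are the reporting conventions
#'   in use); `NULL` for the unrounded percentage.
#' @return percentage.
#' @examples
#' waiting_list_fraction(550, 4327, 227, digits = 0)  # 12
#' waiting_list_fraction(930, 4424, 346)              # 19.5
#' @export
waiting_list_fraction <- function(avg_wl, avg_hd, avg_pd, digits = 1) {
  stopifnot(all(avg_hd + avg_pd > 0), all(avg_wl >= 0))
  pct <- 100 * avg_wl / (avg_hd + avg_pd)
  if (is.null(digits)) pct else round_half_away(pct, digits)
}

#' Deceased- vs living-donor contingency table for two regions
#'
#' Builds the 2x2 table of transplant typology (deceased donor = DBD +
#' DCD, against living donor) for two regions of a period summary, the
#' input to [fisher_exact_2x2()].
#'
#' @param summary period summary from [aggregate_period()].
#' @param region_a,region_b region identifiers present in `summary`.
#' @return 2x2 integer matrix with regions as rows and columns
#'   `ktdd`, `ktld`.
#' @examples
#' study_registry() |>
#'   aggregate_period(c(2017, 2019)) |>
#'   contingency_2x2("Sicily", "NBench1")
#' @export
contingency_2x2 <- function(summary, region_a, region_b) {
  pick <- function(reg) {
    row <- summary[summary$region == reg, , drop = FALSE]
    if (nrow(row) != 1) {
      abort(paste0("region not found in summary: ", reg),
            class = "ktbench_validation_error")
    }
    c(ktdd = row$ktdd, ktld = row$kt_ld)
  }
  m <- rbind(pick(region_a), pick(region_b))
  dimnames(m) <- list(c(region_a, region_b), c("ktdd", "ktld"))
  storage.mode(m) <- "integer"
  m
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration over all tables
#' with the observed margins, summing the probabilities of tables no more
#' likely than the observed one (the minimum-likelihood rule of
#' [stats::fisher.test()], which performs the computation). A degenerate
#' table — an all-zero row or column — carries no information and returns
#' p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts, e.g. from
#'   [contingency_2x2()].
#' @return list with `p_value` (exact) and `p_rounded` (4 decimals,
#'   half-away), the reporting precision of the typology comparison.
#' @examples
#' fisher_exact_2x2(matrix(c(350, 29, 639, 109), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == floor(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warn("degenerate margin: a row or column of the table is all zero; p = 1")
    return(list(p_value = 1, p_rounded = 1))
  }
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  p <- min(p, 1)
  list(p_value = p, p_rounded = round_half_away(p, 4))
}

#' Typology comparison of a reference region against benchmarks
#'
#' For each benchmark region, tests whether the deceased- vs living-donor
#' transplant mix differs from the reference region (two-sided Fisher
#' exact test on the period totals).
#'
#' @param summary period summary from [aggregate_period()].
#' @param reference region compared against every other region.
#' @return tibble with columns `region`, `ktdd`, `ktld`, `p_value`
#'   (exact; NA on the reference row), `p_label` (4-decimal label,
#'   `"<0.0001"` below the reporting floor).
#' @examples
#' study_registry() |>
#'   aggregate_period(c(2017, 2019)) |>
#'   typology_test("Sicily")
#' @export
typology_test <- function(summary, reference = summary$region[1]) {
  stopifnot(reference %in% summary$region)
  others <- setdiff(summary$region, reference)
  rows <- purrr::map_dfr(others, function(reg) {
    p <- fisher_exact_2x2(contingency_2x2(summary, reference, reg))$p_value
    tibble::tibble(region = reg, p_value = p)
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(region = character(), p_value = double())
  }
  out <- summary |>
    dplyr::select("region", "ktdd", ktld = "kt_ld") |>
    dplyr::left_join(rows, by = "region") |>
    dplyr::arrange(.data$region != reference)
  out$p_label <- dplyr::case_when(
    is.na(out$p_value) ~ "//",
    out$p_value < 1e-4 ~ "<0.0001",
    TRUE ~ formatC(round_half_away(out$p_value, 4), format = "f", digits = 4)
  )
  out
}

#' Kidneys and organs lost to a utilized-donor deficit
#'
#' In the study setting each utilized donor yields on average three
#' transplantable organs, and five utilized donors lead to eight kidney
#' transplants. A deficit of `ud_deficit` donors therefore costs
#' `3 * ud_deficit` organs and `8/5 * ud_deficit` kidneys; the integer
#' `kidneys_lost` is the floor of the latter, a lower bound.
#'
#' @param ud_deficit utilized donors lost (>= 0).
#' @return tibble with columns `ud_deficit`, `organs_lost`,
#'   `kidneys_lost_exact`, `kidneys_lost` (floor, "at least" figure).
#' @examples
#' organ_yield_estimate(5)   # 8 kidneys
#' organ_yield_estimate(66)  # 105.6 exact, at least 105
#' @export
organ_yield_estimate <- function(ud_deficit) {
  stopifnot(all(ud_deficit >= 0))
  tibble::tibble(
    ud_deficit = ud_deficit,
    organs_lost = 3 * ud_deficit,
    kidneys_lost_exact = 8 / 5 * ud_deficit,
    kidneys_lost = floor(8 / 5 * ud_deficit)
  )
}
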