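#' @section Registry schema:
#' A registry is a tibble with one row per region-year and columns
#' `region`, `year`, `population`, `ud_dbd`, `ud_dcd`, `kt_dbd`, `kt_dcd`,
#' `kt_ld`, `rrt_hd`, `rrt_pd`, `rrt_kt`, `waiting_list`, plus the derived
#' totals `ud_total` and `kt_total`. Counts are non-negative integers;
#' missing cells use NA. Within a region, years must be consecutive with
#' no duplicates.
#' @name registry-schema
#' @keywords internal
NULL

# canonical column order; everything after `year` may be NA
.registry_cols <- c(
  "region", "year", "population",
  "ud_dbd", "ud_dcd", "kt_dbd", "kt_dcd", "kt_ld",
  "rrt_hd", "rrt_pd", "rrt_kt", "waiting_list"
)
.count_cols <- c(
  "ud_dbd", "ud_dcd", "kt_dbd", "kt_dcd", "kt_ld",
  "rrt_hd", "rrt_pd", "rrt_kt", "waiting_list"
)

#' Load a regional activity registry from delimited text
#'
#' Reads one row per region-year (comma- or tab-delimited, `NA` token for
#' missing cells, `#` comment lines allowed), validates every record, and
#' returns a tidy registry tibble with derived totals.
#'
#' @param source path to a delimited-text file, or a data frame already in
#'   the registry schema.
#' @return A tibble in the registry schema (see [registry-schema]) with
#'   derived columns `ud_total = ud_dbd + ud_dcd` and
#'   `kt_total = kt_dbd + kt_dcd + kt_ld`, sorted by region and year.
#'   An empty source yields an empty registry, not an error.
#' @seealso [validate_registry()] for the underlying checks,
#'   [write_registry()] for the inverse, [study_registry()] for the
#'   bundled study tables.
#' @examples
#' reg <- study_registry()
#' dplyr::filter(reg, region == "Sicily")$kt_total
#' @export
load_registry <- function(source) {
  if (is.data.frame(source)) {
    df <- tibble::as_tibble(source)
  } else {
    stopifnot(is.character(source), length(source) == 1)
    if (!file.exists(source)) {
      abort(paste0("registry file not found: ", source), class = "ktbench_io_error")
    }
    df <- readr::read_delim(
      source,
      delim = NULL, na = "NA", comment = "#",
      show_col_types = FALSE, trim_ws = TRUE,
      col_types = readr::cols(
        region = readr::col_character(),
        .default = readr::col_double()
      )
    )
  }
  as_registry(df)
}

#' Coerce and validate a data frame as a registry
#'
#' @param df data frame in the registry schema.
#' @return validated registry tibble with derived totals.
#' @export
as_registry <- function(df) {
  missing_cols <- setdiff(.registry_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(
      paste0("registry is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "ktbench_validation_error"
    )
  }
  df <- dplyr::select(tibble::as_tibble(df), dplyr::all_of(.registry_cols))
  if (nrow(df) == 0) {
    df$ud_total <- double()
    df$kt_total <- double()
    return(df)
  }
  problems <- validate_registry(df)
  if (nrow(problems) > 0) {
    msgs <- sprintf(
      "row %s, field %s: %s", problems$row, problems$field, problems$problem
    )
    abort(
      c("invalid registry:", setNames(msgs, rep("x", length(msgs)))),
      class = "ktbench_validation_error"
    )
  }
  # regions keep their first-appearance order (the reference region leads)
  df |>
    dplyr::mutate(
      dplyr::across(dplyr::all_of(c("year", .count_cols)), as.integer),
      ud_total = .data$ud_dbd + .data$ud_dcd,
      kt_total = .data$kt_dbd + .data$kt_dcd + .data$kt_ld
    ) |>
    dplyr::arrange(match(.data$region, unique(.data$region)), .data$year)
}

#' List schema violations in a registry table
#'
#' Checks every record invariant — non-negative integer counts, positive
#' population, unique region-years, consecutive years within a region —
#' and reports each violation with the offending row and field.
#'
#' @param df data frame in the registry schema.
#' @return tibble with columns `row`, `region`, `field`, `problem`;
#'   zero rows when the registry is valid.
#' @export
validate_registry <- function(df) {
  df <- tibble::as_tibble(df)
  out <- list()
  bad <- function(rows, field, problem) {
    tibble::tibble(
      row = rows,
      region = as.character(df$region[rows]),
      field = field, problem = problem
    )
  }

  for (col in c("year", .count_cols)) {
    v <- df[[col]]
    i <- which(!is.na(v) & (!is.finite(v) | v < 0))
    if (length(i)) out[[length(out) + 1]] <- bad(i, col, "negative or non-finite count")
    i <- which(!is.na(v) & is.finite(v) & v >= 0 & v != floor(v))
    if (length(i)) out[[length(out) + 1]] <- bad(i, col, "count is not an integer")
  }
  i <- which(is.na(df$year))
  if (length(i)) out[[length(out) + 1]] <- bad(i, "year", "year is missing")
  i <- which(is.na(df$region) | !nzchar(as.character(df$region)))
  if (length(i)) out[[length(out) + 1]] <- bad(i, "region", "region identifier is missing")
  i <- which(!is.na(df$population) & df$population <= 0)
  if (length(i)) out[[length(out) + 1]] <- bad(i, "population", "population must be strictly positive")

  key <- paste(df$region, df$year)
  i <- which(duplicated(key))
  if (length(i)) out[[length(out) + 1]] <- bad(i, "year", "duplicate region-year")

  ok_rows <- !is.na(df$year) & !is.na(df$region)
  for (reg in unique(df$region[ok_rows])) {
    yrs <- sort(df$year[ok_rows & df$region == reg])
    if (length(yrs) > 1 && any(diff(unique(yrs)) != 1)) {
      i <- which(df$region == reg & df$year == yrs[min(which(diff(unique(yrs)) != 1)) + 1])[1]
      out[[length(out) + 1]] <- bad(i, "year", "years are not consecutive")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      row = integer(), region = character(),
      field = character(), problem = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$row)
}

#' Write a registry back to delimited text
#'
#' Inverse of [load_registry()]: emits the schema columns (derived totals
#' dropped) with the literal token `NA` for missing cells, so that a
#' load-write-load round trip is exact.
#'
#' @param registry registry tibble.
#' @param path output file path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  out <- dplyr::select(registry, dplyr::all_of(.registry_cols))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "NA")
  invisible(path)
}

#' Summarise a registry over a period
#'
#' For each region, aggregates consecutive activity years into the period
#' summary used for benchmarking: cumulative transplant counts by typology
#' (with one-decimal percentages of the period total), and arithmetic
#' means of the prevalence and waiting-list snapshots. Missing snapshots
#' are excluded from the means; percentages use half-away-from-zero
#' rounding.
#'
#' @param registry registry tibble from [load_registry()].
#' @param window integer vector of years, or `c(first, last)`; every year
#'   must be present for every region summarised.
#' @return tibble, one row per region, with columns `region`, `year_min`,
#'   `year_max`, `n_years`, `kt_total`, `kt_dbd`, `kt_dcd`, `kt_ld`,
#'   `ktdd` (deceased-donor total = DBD + DCD), `pct_dbd`, `pct_dcd`,
#'   `pct_ld`, `ud_total`, `avg_waiting_list`, `avg_hd`, `avg_pd`,
#'   `avg_rrt_kt`.
#' @examples
#' aggregate_period(study_registry(), c(2017, 2019))
#' @export
aggregate_period <- function(registry, window = range(registry$year)) {
  stopifnot(nrow(registry) > 0)
  years <- if (length(window) == 2) seq(window[1], window[2]) else as.integer(window)
  by_region <- split(registry$year, registry$region)
  for (reg in names(by_region)) {
    if (!all(years %in% by_region[[reg]])) {
      abort(
        sprintf(
          "window %d-%d outside the years recorded for region %s",
          min(years), max(years), reg
        ),
        class = "ktbench_range_error"
      )
    }
  }
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  registry |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      year_min = min(.data$year),
      year_max = max(.data$year),
      n_years = dplyr::n(),
      kt_total = sum(.data$kt_total),
      kt_dbd = sum(.data$kt_dbd),
      kt_dcd = sum(.data$kt_dcd),
      kt_ld = sum(.data$kt_ld),
      ktdd = sum(.data$kt_dbd + .data$kt_dcd),
      ud_total = if (all(is.na(.data$ud_total))) NA_integer_ else sum(.data$ud_total, na.rm = TRUE),
      avg_waiting_list = mean_or_na(.data$waiting_list),
      avg_hd = mean_or_na(.data$rrt_hd),
      avg_pd = mean_or_na(.data$rrt_pd),
      avg_rrt_kt = mean_or_na(.data$rrt_kt),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_dbd = round_half_away(100 * .data$kt_dbd / .data$kt_total, 1),
      pct_dcd = round_half_away(100 * .data$kt_dcd / .data$kt_total, 1),
      pct_ld = round_half_away(100 * .data$kt_ld / .data$kt_total, 1),
      .after = "kt_ld"
    )
}
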