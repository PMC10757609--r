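ktb_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ktbench")
  if (!nzchar(path)) {
    abort(paste0("bundled data file not found: ", file), class = "ktbench_io_error")
  }
  path
}

#' Bundled study registry: Sicily and two benchmark programmes
#'
#' Returns the transcribed 2017-2019 activity tables for Sicily, the
#' national benchmark programme (NBench1) and the international benchmark
#' programme (IBench2): transplants by typology (DBD, DCD, living donor),
#' dialysis and transplant prevalence, and waiting-list snapshots.
#' Utilized-donor counts were never published for these regions — only
#' per-million rates, available via [ud_rate_reference()] — so `ud_dbd`
#' and `ud_dcd` are NA.
#'
#' @param regions which regions to load (any subset of `"Sicily"`,
#'   `"NBench1"`, `"IBench2"`).
#' @return validated registry tibble (see [load_registry()]).
#' @examples
#' study_registry() |> aggregate_period(c(2017, 2019))
#' @export
study_registry <- function(regions = c("Sicily", "NBench1", "IBench2")) {
  regions <- match.arg(regions, several.ok = TRUE)
  files <- c(
    Sicily = "sicily.csv", NBench1 = "nbench1.csv", IBench2 = "ibench2.csv"
  )[regions]
  purrr::map(unname(files), function(f) load_registry(ktb_extdata(f))) |>
    dplyr::bind_rows()
}

#' Regional populations for per-million rates
#'
#' Populations are not part of the published activity tables; the bundled
#' values are back-solved from published per-million rates (documented in
#' the file header) so that those rates round-trip. Treat them as analysis
#' conventions, not census figures.
#'
#' @return tibble with columns `region`, `population`.
#' @export
region_populations <- function() {
  readr::read_csv(
    ktb_extdata("populations.csv"),
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(region = readr::col_character(),
                            population = readr::col_double())
  )
}

#' National donor and transplant rate reference (Italy vs United Kingdom)
#'
#' Published per-million rates of utilized donors and kidney transplants
#' for the two national programmes, 2017-2019, used to establish the
#' comparability of the regional benchmarks. Reference data only.
#'
#' @return tibble with columns `metric`, `year`, `italy`, `uk`.
#' @export
national_rate_reference <- function() {
  readr::read_csv(ktb_extdata("italy_uk_rates.csv"),
                  comment = "#", show_col_types = FALSE)
}

#' Regional utilized-donor rate reference
#'
#' Published UD/pmp rates (total and DBD/DCD split where available) for
#' the study regions. Absolute donor counts were never published.
#'
#' @return tibble with columns `region`, `year`, `ud_pmp`, `ud_dbd_pmp`,
#'   `ud_dcd_pmp`.
#' @export
ud_rate_reference <- function() {
  readr::read_csv(ktb_extdata("ud_rates.csv"),
                  comment = "#", show_col_types = FALSE)
}
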