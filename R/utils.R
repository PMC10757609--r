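#' Round half away from zero
#'
#' Commercial rounding used throughout the reported tables: exact halves
#' move away from zero, unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep (may be negative).
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_away(0.5)    # 1, where round(0.5) is 0
#' round_half_away(12.25, 1)
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon absorbs binary representation error in values such as
  # 12.25 * 10 = 122.49999...
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Format an amount in euros
#'
#' @param x numeric vector of amounts in EUR.
#' @param eu_format logical; if `TRUE`, render in the continental style
#'   (dots as thousands separators, comma as decimal mark), e.g.
#'   `"13.367,6"`; otherwise `"13,367.6"`.
#' @param digits decimal places shown (trailing ",0"/".0" dropped).
#' @return character vector.
#' @examples
#' format_eur(13367.6)
#' format_eur(13367.6, eu_format = TRUE)
#' @export
format_eur <- function(x, eu_format = FALSE, digits = 1) {
  x <- round_half_away(x, digits)
  out <- formatC(x, format = "f", digits = digits, big.mark = ",")
  out <- sub("\\.0+$", "", out)
  if (eu_format) {
    out <- vapply(out, function(s) {
      s <- gsub(",", "\035", s, fixed = TRUE)
      s <- sub(".", ",", s, fixed = TRUE)
      gsub("\035", ".", s, fixed = TRUE)
    }, character(1), USE.NAMES = FALSE)
  }
  out
}
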