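#' Round half away from zero
#'
#' Published tables round halves away from zero (e.g. 2980.8 -> 2981,
#' -1101.6 -> -1102), whereas [base::round()] rounds halves to even. All
#' report-facing rounding in this package goes through this helper; internal
#' computation always keeps full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @examples
#' round_half_up(c(0.465, -1.095, 2980.8), c(2, 2, 0))
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # tiny eps guards against representation error just below .5
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# shared input check: a data frame with required columns
check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    stop(sprintf("`%s` must be a data frame", what), call. = FALSE)
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "`%s` is missing column(s): %s", what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}
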