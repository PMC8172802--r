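#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used by most clinical reporting software (base R's [round()]
#' rounds ties to even).  A small epsilon guards against values such as
#' `2.405` being stored as `2.40499...` in binary floating point.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(2.405, 2) # 2.41, where round() gives 2.4
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

#' Round an effect estimate the way disproportionality tools display it
#'
#' Reporting odds ratios and their confidence bounds in published
#' pharmacovigilance screens are typically displayed after half-up rounding
#' through a one-extra-digit intermediate (a value of 4.2847 is first carried
#' at 4.285 and then shown as 4.29).  `report_round()` reproduces that display
#' convention so that package output can be compared digit-for-digit with
#' published tables.  Internal computation is always at full precision;
#' this is a formatting step only.
#'
#' @param x Numeric vector of estimates.
#' @param digits Decimal places in the final display (default 2).
#' @return Numeric vector rounded for display.
#' @export
#' @examples
#' report_round(4.2847) # 4.29
#' round(4.2847, 2)     # 4.28 -- plain rounding differs
report_round <- function(x, digits = 2) {
  round_half_up(round_half_up(x, digits + 1), digits)
}

# shared input check: a single non-missing number
check_number <- function(x, what, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", what))
  }
  if (x < min) abort(sprintf("`%s` must be >= %s.", what, format(min)))
  invisible(x)
}

# case-fold and squish whitespace; the package's single string-normal form
norm_string <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}
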