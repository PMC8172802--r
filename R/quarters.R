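#' Calendar-quarter labels
#'
#' Quarterly series throughout the package are indexed by labels of the form
#' `"YYYYQn"` (`n` in 1..4), e.g. `"2007Q1"`.  `as_quarter()` validates and
#' normalizes such labels (also accepting [zoo::yearqtr] input and monthly
#' `"YYYY-MM"` periods, which are mapped to their containing quarter);
#' `quarter_seq()` enumerates the quarters of an inclusive window.
#'
#' @param x Character vector of quarter labels, monthly `"YYYY-MM"` periods,
#'   or a [zoo::yearqtr] vector.
#' @return `as_quarter()`: a character vector of normalized `"YYYYQn"` labels.
#' @export
#' @examples
#' as_quarter("2010-05")           # "2010Q2"
#' quarter_seq("2007Q1", "2007Q4") # four labels
#' length(quarter_seq("2007Q1", "2020Q2")) # 54
as_quarter <- function(x) {
  if (inherits(x, "yearqtr")) {
    return(format(x, "%YQ%q"))
  }
  x <- stringr::str_squish(as.character(x))
  out <- character(length(x))
  is_q <- stringr::str_detect(x, "^[0-9]{4}Q[1-4]$")
  is_m <- stringr::str_detect(x, "^[0-9]{4}-(0[1-9]|1[0-2])$")
  bad <- !is_q & !is_m & !is.na(x)
  if (any(bad)) {
    abort(sprintf(
      "Malformed period label(s): %s. Expected \"YYYYQn\" or \"YYYY-MM\".",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  out[is_q] <- x[is_q]
  if (any(is_m)) {
    yr <- substr(x[is_m], 1, 4)
    mo <- as.integer(substr(x[is_m], 6, 7))
    out[is_m] <- sprintf("%sQ%d", yr, (mo - 1L) %/% 3L + 1L)
  }
  out[is.na(x)] <- NA_character_
  out
}

#' @rdname as_quarter
#' @param from,to Window endpoints, inclusive, as `"YYYYQn"` labels.
#' @return `quarter_seq()`: the ordered character vector of quarters from
#'   `from` to `to`.
#' @export
quarter_seq <- function(from, to) {
  from_q <- zoo::as.yearqtr(as_quarter(from), format = "%YQ%q")
  to_q <- zoo::as.yearqtr(as_quarter(to), format = "%YQ%q")
  if (is.na(from_q) || is.na(to_q)) abort("Window endpoints must be valid quarters.")
  if (from_q > to_q) abort("Window start lies after window end.")
  format(seq(from_q, to_q, by = 1 / 4), "%YQ%q")
}

# validate a length-2 inclusive window, returning normalized labels
check_window <- function(window) {
  if (length(window) != 2L) abort("`window` must be c(from, to).")
  w <- as_quarter(window)
  quarter_seq(w[1], w[2]) # errors if reversed/malformed
  w
}
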