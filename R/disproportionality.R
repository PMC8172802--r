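#' 2x2 contingency table of report counts
#'
#' The unit of disproportionality analysis: `a` reports with drug and event
#' category, `b` with drug only, `c` with category only, `d` with neither.
#'
#' @param a,b,c,d Non-negative integer cell counts; at least one positive.
#' @return A `contingency_table` (named list `a`, `b`, `c`, `d`, `n`).
#' @seealso [table_from_marginals()], [compute_ror()]
#' @export
contingency_table <- function(a, b, c, d) {
  for (nm in c("a", "b", "c", "d")) {
    v <- get(nm)
    check_number(v, nm, min = 0)
    if (abs(v - round(v)) > 1e-8) abort(sprintf("Cell `%s` must be an integer count.", nm))
  }
  if (a + b + c + d < 1) abort("The table must contain at least one report.")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  lab <- c(attr(x, "drug"), attr(x, "category"))
  if (length(lab)) cat(sprintf("# %s\n", paste(lab, collapse = " x ")))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "other drugs"), c("event", "other events")))
  print(m)
  invisible(x)
}

#' Build a 2x2 table from published marginal counts
#'
#' Published disproportionality screens usually print only the grand total,
#' the per-drug and per-category report counts and the co-report count;
#' the four cells are forced by that arithmetic:
#' `a = n_combination`, `b = n_drug - a`, `c = n_category - a`,
#' `d = n_total - n_drug - n_category + a`.
#'
#' @param n_total Grand total number of reports in the database.
#' @param n_drug Reports mentioning the drug.
#' @param n_category Reports mentioning the event category.
#' @param n_combination Reports mentioning both.
#' @return A [contingency_table()].
#' @export
#' @examples
#' table_from_marginals(7430750, 107905, 118980, 4558)
table_from_marginals <- function(n_total, n_drug, n_category, n_combination) {
  check_number(n_total, "n_total", min = 0)
  check_number(n_drug, "n_drug", min = 0)
  check_number(n_category, "n_category", min = 0)
  check_number(n_combination, "n_combination", min = 0)
  if (n_combination > n_drug) {
    abort("Inconsistent marginals: n_combination exceeds n_drug.")
  }
  if (n_combination > n_category) {
    abort("Inconsistent marginals: n_combination exceeds n_category.")
  }
  if (n_drug + n_category - n_combination > n_total) {
    abort("Inconsistent marginals: n_drug + n_category - n_combination exceeds n_total.")
  }
  contingency_table(
    a = n_combination,
    b = n_drug - n_combination,
    c = n_category - n_combination,
    d = n_total - n_drug - n_category + n_combination
  )
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' The reporting odds ratio ROR = (a d) / (b c) quantifies how
#' disproportionately a drug and an event category are co-reported relative
#' to the rest of the database.  The confidence interval is the Woolf
#' log-normal interval `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' The signal criterion is evaluated alongside: a pair is a signal when the
#' co-report count exceeds 3 and the CI lower bound exceeds 1 (both strict);
#' see [detect_signal()].
#'
#' Zero cells: with `b = 0` or `c = 0` the ROR is undefined and an error is
#' raised unless `correction = TRUE`, which adds the Haldane--Anscombe 0.5
#' to every cell.  With `a = 0` or `d = 0` but `b, c > 0`, the (zero)
#' estimate is returned with the CI flagged unavailable; a zero estimate is
#' never a signal.
#'
#' @param table A [contingency_table()].
#' @param z Normal quantile for the interval; default 1.96 (the conventional
#'   95% value, as used in published screens).
#' @param correction Apply the 0.5 continuity correction to all cells?
#'   Default `FALSE`.
#' @return A one-row tibble of class `ror_result`: `n_combination`, `ror`,
#'   `ci_low`, `ci_high`, `ci_available`, `is_signal` (plus `drug`/`category`
#'   columns when the table carries those attributes).
#' @export
#' @examples
#' compute_ror(table_from_marginals(7430750, 107905, 118980, 4558))
compute_ror <- function(table, z = 1.96, correction = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  check_number(z, "z", min = 0)
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  n_combination <- a
  if (correction && (a == 0 || b == 0 || c_ == 0 || d == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  if (b == 0 || c_ == 0) {
    abort("undefined ROR: a zero `b` or `c` cell (consider `correction = TRUE`).")
  }
  ror <- (a * d) / (b * c_)
  if (a > 0 && d > 0) {
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    ci_low <- exp(log(ror) - z * se)
    ci_high <- exp(log(ror) + z * se)
    ci_available <- TRUE
  } else {
    ci_low <- NA_real_
    ci_high <- NA_real_
    ci_available <- FALSE
  }
  is_signal <- if (ci_available) {
    detect_signal(n_combination = n_combination, ci_low = ci_low)
  } else {
    FALSE # CI only unavailable when the estimate is 0, which never signals
  }
  out <- tibble::tibble(
    n_combination = n_combination, ror = ror,
    ci_low = ci_low, ci_high = ci_high,
    ci_available = ci_available, is_signal = is_signal
  )
  drug <- attr(table, "drug"); category <- attr(table, "category")
  if (!is.null(drug)) out <- tibble::add_column(out, drug = drug, .before = 1)
  if (!is.null(category)) {
    out <- tibble::add_column(out, category = category, .after = if (is.null(drug)) 0L else 1L)
  }
  class(out) <- c("ror_result", class(out))
  out
}

#' Safety-signal criterion
#'
#' A drug--event pair is flagged as a safety signal when the number of
#' co-reports is greater than 3 and the lower bound of the 95% confidence
#' interval of the ROR is greater than 1 -- both strict inequalities, so a
#' pair with exactly 3 co-reports does not signal however large its ROR.
#'
#' @param result A `ror_result` row from [compute_ror()]; alternatively
#'   supply `n_combination` and `ci_low` directly.
#' @param n_combination,ci_low Components of the criterion, used when
#'   `result` is missing.
#' @return Logical.
#' @export
#' @examples
#' detect_signal(n_combination = 4558, ci_low = 2.70) # TRUE
#' detect_signal(n_combination = 3, ci_low = 5)       # FALSE (strict > 3)
detect_signal <- function(result = NULL, n_combination = NULL, ci_low = NULL) {
  if (!is.null(result)) {
    if (!all(c("n_combination", "ci_low") %in% names(result))) {
      abort("`result` must carry `n_combination` and `ci_low`.")
    }
    if (any(!result$ci_available %||% TRUE) || anyNA(result$ci_low)) {
      abort("Signal detection needs an available confidence interval.")
    }
    n_combination <- result$n_combination
    ci_low <- result$ci_low
  }
  n_combination > 3 & ci_low > 1
}

#' Screen every drug x category pair
#'
#' Runs [compute_ror()] over all pairs of drugs and term categories, either
#' from a tibble of published marginal counts (columns `drug`, `category`,
#' `n_drug`, `n_category`, `n_combination`, `n_total`) or from a
#' [report_store()] by counting the marginals with [count_marginals()].
#' Rows are ordered drugs x categories (vocabulary order for a store, input
#' order for marginals).
#'
#' @param x A marginals tibble or a `report_store`.
#' @param drugs,categories Character vectors selecting/ordering the pairs;
#'   default: all drugs and categories of `vocab` (store input) or all pairs
#'   present (marginals input).
#' @param vocab A `vigicross_vocab`; used for store input.
#' @inheritParams compute_ror
#' @return A tibble of class `ror_screen`: one `ror_result` row per pair
#'   with columns `drug`, `category`, `n_combination`, `ror`, `ci_low`,
#'   `ci_high`, `ci_available`, `is_signal`.
#' @seealso [faers_marginals()] for the packaged published counts;
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' screen <- ror_screen(faers_marginals())
#' dplyr::filter(screen, category == "drug_abuse_and_dependence")
ror_screen <- function(x, drugs = NULL, categories = NULL,
                       vocab = default_vocab(), z = 1.96, correction = FALSE) {
  if (inherits(x, "report_store")) {
    drugs <- drugs %||% vocab$drugs$generic_name
    categories <- categories %||% vocab$categories$name
    pairs <- tidyr::expand_grid(drug = drugs, category = categories)
    res <- purrr::pmap(pairs, function(drug, category) {
      compute_ror(count_marginals(x, drug, category, vocab), z = z, correction = correction)
    })
  } else {
    x <- tibble::as_tibble(x)
    needed <- c("drug", "category", "n_drug", "n_category", "n_combination", "n_total")
    if (!all(needed %in% names(x))) {
      abort(sprintf("Marginals input needs columns %s.", paste(needed, collapse = ", ")))
    }
    if (!is.null(drugs)) x <- dplyr::filter(x, .data$drug %in% drugs)
    if (!is.null(categories)) x <- dplyr::filter(x, .data$category %in% categories)
    res <- purrr::pmap(x, function(drug, category, n_drug, n_category,
                                   n_combination, n_total, ...) {
      tab <- table_from_marginals(n_total, n_drug, n_category, n_combination)
      attr(tab, "drug") <- drug
      attr(tab, "category") <- category
      compute_ror(tab, z = z, correction = correction)
    })
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("ror_screen", setdiff(class(out), "ror_result"))
  out
}

#' Quarterly ROR series for one drug x category pair
#'
#' Applies [compute_ror()] to the reports of each window quarter separately.
#' Quarters whose 2x2 table fails the ROR preconditions (zero `b` or `c`
#' cell, or no reports) yield missing values rather than errors, so sparse
#' early quarters do not break a timeline.
#'
#' @inheritParams count_marginals
#' @inheritParams compute_ror
#' @return Tibble with columns `quarter`, `n_combination`, `ror`, `ci_low`,
#'   `ci_high`, `is_signal` (NA-filled where undefined).
#' @export
quarterly_ror <- function(store, drug, category, vocab = default_vocab(), z = 1.96) {
  stopifnot(inherits(store, "report_store"))
  fl <- store_flags(store, drug, category, vocab)
  quarters <- quarter_seq(store$window[1], store$window[2])
  purrr::map_dfr(quarters, function(q) {
    sel <- store$reports$quarter == q
    a <- sum(fl$has_drug[sel] & fl$has_evt[sel])
    b <- sum(fl$has_drug[sel] & !fl$has_evt[sel])
    c_ <- sum(!fl$has_drug[sel] & fl$has_evt[sel])
    d <- sum(!fl$has_drug[sel] & !fl$has_evt[sel])
    if (sum(sel) == 0L || b == 0 || c_ == 0) {
      return(tibble::tibble(quarter = q, n_combination = a, ror = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_, is_signal = NA))
    }
    r <- compute_ror(contingency_table(a, b, c_, d), z = z)
    tibble::tibble(quarter = q, n_combination = r$n_combination, ror = r$ror,
                   ci_low = r$ci_low, ci_high = r$ci_high, is_signal = r$is_signal)
  })
}

#' Packaged published FAERS marginal counts (2007--2020Q2)
#'
#' Aggregate marginal counts for the four study drugs and five abuse-related
#' term categories, as published from a cleaned FAERS extract covering
#' 2007Q1--2020Q2 (grand total 7,430,750 reports).  These printed counts let
#' the full disproportionality screen be reproduced without any report-level
#' data: `ror_screen(faers_marginals())`.
#'
#' @return Tibble with columns `drug`, `category`, `n_drug`, `n_category`,
#'   `n_combination`, `n_total` (20 rows).
#' @export
faers_marginals <- function() {
  path <- system.file("extdata", "faers_marginals_2007_2020q2.csv",
                      package = "vigicross", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccdddd")
}

#' @export
tidy.ror_screen <- function(x, conf.int = TRUE, ...) {
  out <- tibble::as_tibble(x)
  out <- dplyr::rename(out, estimate = "ror", conf.low = "ci_low", conf.high = "ci_high")
  if (!conf.int) out <- dplyr::select(out, -"conf.low", -"conf.high")
  out
}

#' @export
glance.ror_screen <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_signals = sum(x$is_signal, na.rm = TRUE),
    n_ci_unavailable = sum(!x$ci_available)
  )
}

#' @export
autoplot.ror_screen <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$drug <- factor(df$drug, levels = rev(unique(df$drug)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$drug,
                                   colour = .data$is_signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "Reporting odds ratio (log scale)", y = NULL,
                  colour = "Signal") +
    ggplot2::theme_minimal()
}

#' Format a screen for publication-style display
#'
#' Applies [report_round()] to the estimate and CI columns so the numbers
#' match published two-decimal tables digit for digit.
#'
#' @param screen A `ror_screen` (or `ror_result`).
#' @param digits Decimal places (default 2).
#' @return Tibble with rounded `ror`, `ci_low`, `ci_high`.
#' @export
format_screen <- function(screen, digits = 2) {
  dplyr::mutate(
    tibble::as_tibble(screen),
    dplyr::across(dplyr::any_of(c("ror", "ci_low", "ci_high")),
                  ~ report_round(.x, digits))
  )
}
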