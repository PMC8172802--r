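#' Align two quarterly series on their common quarters
#'
#' Pairs two quarterly series on the intersection of their quarters,
#' dropping any quarter where either value is missing (pairwise-complete).
#' Fewer than three shared complete quarters is an error: no meaningful
#' rank correlation exists below that.
#'
#' @param x,y Tibbles whose first column is `quarter` and whose second
#'   column holds the values (any column names).
#' @return Tibble with columns `quarter`, `x`, `y`; attribute
#'   `dropped_quarters` lists the quarters removed for missingness.
#' @export
align_series <- function(x, y) {
  grab <- function(s, nm) {
    s <- tibble::as_tibble(s)
    if (!"quarter" %in% names(s)) abort(sprintf("`%s` needs a `quarter` column.", nm))
    val <- setdiff(names(s), "quarter")[1]
    if (is.na(val)) abort(sprintf("`%s` needs a value column.", nm))
    tibble::tibble(quarter = as_quarter(s$quarter), value = as.numeric(s[[val]]))
  }
  xs <- grab(x, "x"); ys <- grab(y, "y")
  paired <- dplyr::inner_join(xs, ys, by = "quarter", suffix = c("_x", "_y")) |>
    dplyr::arrange(zoo::as.yearqtr(.data$quarter, format = "%YQ%q"))
  complete <- !is.na(paired$value_x) & !is.na(paired$value_y)
  dropped <- paired$quarter[!complete]
  paired <- paired[complete, ]
  if (nrow(paired) < 3L) {
    abort("insufficient overlap: fewer than 3 shared complete quarters.")
  }
  out <- tibble::tibble(quarter = paired$quarter, x = paired$value_x, y = paired$value_y)
  attr(out, "dropped_quarters") <- dropped
  out
}

# two-sided p for a Spearman rho under the t-approximation on n - 2 df
rho_pvalue <- function(rho, n) {
  if (abs(rho) >= 1) return(.Machine$double.xmin)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t_stat), df = n - 2)
}

#' Spearman rank correlation with a two-sided p-value
#'
#' Computes rho as the Pearson correlation of average ranks (ties receive
#' their mean rank) and, by default, a two-sided p-value from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom -- the standard approximation at the series lengths
#' quarterly surveillance produces (n around 50).  For tiny samples an
#' exact permutation p-value is available (`p_method = "permutation"`,
#' n <= 8), enumerating all `n!` orderings.  A rho of exactly +/-1 under
#' the t-method is reported with the smallest positive double rather than
#' 0, as the p-value is bounded away from zero only by machine precision.
#'
#' @param x Paired numeric vector, or an aligned tibble from
#'   [align_series()] (columns `x`, `y`).
#' @param y Paired numeric vector when `x` is a vector.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @return One-row tibble of class `correlation_result`: `rho`, `n`,
#'   `p_two_sided`, `p_method`.
#' @export
#' @examples
#' spearman_cor(1:4, c(10, 20, 30, 40))$rho # 1
spearman_cor <- function(x, y = NULL, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  if (is.null(y)) {
    stopifnot(is.data.frame(x), all(c("x", "y") %in% names(x)))
    y <- x$y
    x <- x$x
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort("Spearman correlation needs at least 3 paired values.")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("rho undefined: zero variance in a rank vector.")
  }
  rho <- cor(rx, ry)
  p <- if (p_method == "t") {
    rho_pvalue(rho, n)
  } else {
    if (n > 8L) abort("Exact permutation p is limited to n <= 8.")
    perms <- all_perms(n)
    rho_perm <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  out <- tibble::tibble(rho = rho, n = n, p_two_sided = p, p_method = p_method)
  class(out) <- c("correlation_result", class(out))
  out
}

# all permutations of 1..n as an n! x n matrix (recursive; n <= 8)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Consistency check between a correlation coefficient and its p-value
#'
#' Recomputes the two-sided p-value a given Spearman rho implies under the
#' t-approximation at sample size `n` -- useful for verifying published
#' (r, p) pairs when the underlying series are not available.
#'
#' @param rho Correlation in (-1, 1).
#' @param n Paired sample size, at least 4.
#' @return The two-sided p-value.
#' @export
#' @examples
#' pvalue_from_rho(0.295, 54) # ~0.030
pvalue_from_rho <- function(rho, n) {
  check_number(rho, "rho")
  check_number(n, "n", min = 4)
  if (abs(rho) >= 1) abort("`rho` must lie strictly inside (-1, 1).")
  rho_pvalue(rho, n)
}

#' Correlate the report domain with the search domain, per drug
#'
#' For each drug, aligns its quarterly report-domain series (co-report
#' counts of the primary term by default, or quarterly RORs) with its
#' quarterly cumulative abuse-SPS series, and computes the Spearman
#' correlation.  Drugs flagged insufficient (no SPS series, or overlap
#' below 3 quarters) get a status row rather than an error, mirroring how
#' low-search-volume drugs drop out of published analyses.
#'
#' @param faers Named list of quarterly tibbles (`quarter`, value) per
#'   drug, e.g. from [quarterly_counts()].
#' @param sps Named list of cumulative SPS tibbles per drug, e.g. from
#'   [cumulative_abuse_sps()]; use `NULL` entries (or empty tibbles) for
#'   drugs without data.
#' @param faers_series_kind,sps_series_kind Labels recorded in the output.
#' @return Tibble of class `cross_domain_cor`: columns `drug`, `n`, `rho`,
#'   `p_two_sided`, `status` (`"ok"` or `"insufficient data"`),
#'   `faers_series_kind`, `sps_series_kind`, `dropped_quarters`
#'   (list-column).
#' @export
correlate_domains <- function(faers, sps,
                              faers_series_kind = "quarterly co-report counts",
                              sps_series_kind = "cumulative abuse SPS") {
  stopifnot(is.list(faers), is.list(sps), !is.null(names(faers)))
  rows <- purrr::map(names(faers), function(drug) {
    s <- sps[[drug]]
    base <- tibble::tibble(
      drug = drug, n = NA_integer_, rho = NA_real_, p_two_sided = NA_real_,
      status = "insufficient data",
      faers_series_kind = faers_series_kind, sps_series_kind = sps_series_kind,
      dropped_quarters = list(character())
    )
    if (is.null(s) || nrow(tibble::as_tibble(s)) == 0L) return(base)
    aligned <- tryCatch(align_series(faers[[drug]], s), error = function(e) NULL)
    if (is.null(aligned)) return(base)
    r <- tryCatch(spearman_cor(aligned), error = function(e) NULL)
    if (is.null(r)) return(base)
    dplyr::mutate(base, n = r$n, rho = r$rho, p_two_sided = r$p_two_sided,
                  status = "ok",
                  dropped_quarters = list(attr(aligned, "dropped_quarters")))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cross_domain_cor", class(out))
  out
}

#' @export
tidy.cross_domain_cor <- function(x, ...) {
  dplyr::rename(tibble::as_tibble(x), estimate = "rho", p.value = "p_two_sided")
}

#' @export
glance.cross_domain_cor <- function(x, ...) {
  tibble::tibble(
    n_drugs = nrow(x),
    n_correlated = sum(x$status == "ok"),
    n_significant = sum(x$status == "ok" & x$p_two_sided < 0.05)
  )
}

#' @export
autoplot.cross_domain_cor <- function(object, ...) {
  df <- tibble::as_tibble(object) |> dplyr::filter(.data$status == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$drug)) +
    ggplot2::geom_col(width = 0.5, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Spearman rho (report domain vs search domain)", y = NULL) +
    ggplot2::xlim(-1, 1) +
    ggplot2::theme_minimal()
}
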