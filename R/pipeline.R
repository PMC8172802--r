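#' Run the full disproportionality screen and write its report
#'
#' Orchestrates the report-domain analysis end to end: takes either a
#' marginal-count table (published or computed) or report-level data,
#' screens every drug x category pair, and optionally writes the standard
#' report CSV (`drug, category, n_combination, ror, ci_low, ci_high,
#' is_signal`, deterministic row order).
#'
#' @param marginals Marginals tibble or CSV path (columns `drug`,
#'   `category`, `n_drug`, `n_category`, `n_combination`, `n_total`).
#' @param reports A [report_store()], or a report CSV/JSONL path (read with
#'   [read_reports()], normalized and cleaned).  Exactly one of
#'   `marginals`/`reports` must be given.
#' @param vocab A `vigicross_vocab`.
#' @param window Analysis window used when reading report-level data.
#' @param out Optional output CSV path.
#' @inheritParams compute_ror
#' @return The `ror_screen` tibble, invisibly when `out` is written.
#' @export
run_ror <- function(marginals = NULL, reports = NULL, vocab = default_vocab(),
                    window = c("2007Q1", "2020Q2"), out = NULL, z = 1.96,
                    correction = FALSE) {
  if (is.null(marginals) == is.null(reports)) {
    abort("Provide exactly one of `marginals` or `reports`.")
  }
  if (!is.null(marginals)) {
    if (is.character(marginals)) {
      if (!file.exists(marginals)) abort(sprintf("Marginals file not found: %s", marginals))
      marginals <- readr::read_csv(marginals, col_types = "ccdddd")
    }
    screen <- ror_screen(marginals, vocab = vocab, z = z, correction = correction)
  } else {
    if (is.character(reports)) {
      if (!file.exists(reports)) abort(sprintf("Report file not found: %s", reports))
      reports <- read_reports(reports) |>
        report_store(window = window) |>
        normalize_drug_names(vocab)
    }
    stopifnot(inherits(reports, "report_store"))
    if (n_reports(reports) == 0L) abort("The report store is empty.")
    screen <- ror_screen(reports, vocab = vocab, z = z, correction = correction)
  }
  if (!is.null(out)) {
    readr::write_csv(
      dplyr::select(tibble::as_tibble(screen), "drug", "category",
                    "n_combination", "ror", "ci_low", "ci_high", "is_signal"),
      out
    )
    return(invisible(screen))
  }
  screen
}

#' Reproduce the published screen from the packaged marginals
#'
#' Convenience wrapper: [run_ror()] on [faers_marginals()].  With
#' [format_screen()] applied, the output matches the published two-decimal
#' table digit for digit.
#'
#' @inheritParams run_ror
#' @return The `ror_screen` tibble.
#' @export
reference_screen <- function(out = NULL) {
  run_ror(marginals = faers_marginals(), out = out)
}

#' Run the cross-domain correlation analysis and write its report
#'
#' For each vocabulary drug: builds the quarterly report-domain series
#' (co-report counts of the primary term, or quarterly RORs), builds the
#' search-domain series (abuse-query filtering, volume floor, SPS
#' normalization, cumulative timeline), and correlates the two with
#' Spearman's method.  Drugs whose abuse-query volume falls under the floor
#' are reported as `"insufficient data"` rows rather than dropped silently.
#'
#' @param store A [report_store()] with normalized drug names.
#' @param query_log Query records (columns `query`, `period`, `count`), or
#'   a CSV path for [read_query_log()].
#' @param vocab A `vigicross_vocab`.
#' @param faers_series `"counts"` (default) or `"ror"`: which quarterly
#'   report-domain series to correlate.
#' @param volume_floor Minimum total abuse-query volume per drug (default
#'   0, i.e. no floor); see [apply_volume_floor()].
#' @param suppress_share SPS suppression share (default 0.01).
#' @param out Optional output CSV path.
#' @return A `cross_domain_cor` tibble, invisibly when `out` is written.
#' @export
run_correlation <- function(store, query_log, vocab = default_vocab(),
                            faers_series = c("counts", "ror"),
                            volume_floor = 0, suppress_share = 0.01,
                            out = NULL) {
  faers_series <- match.arg(faers_series)
  stopifnot(inherits(store, "report_store"))
  if (is.character(query_log)) query_log <- read_query_log(query_log)
  query_log <- tibble::as_tibble(query_log)
  primary <- vocab$categories$name[vocab$categories$scope == "primary"]

  faers <- list()
  sps <- list()
  for (d in vocab$drugs$generic_name) {
    faers[[d]] <- if (faers_series == "counts") {
      quarterly_counts(store, d, primary, vocab)
    } else {
      dplyr::select(quarterly_ror(store, d, primary, vocab), "quarter", "ror")
    }
    abuse <- filter_abuse_queries(query_log, d, vocab = vocab)
    abuse <- apply_volume_floor(abuse, volume_floor)
    if (insufficient_data(abuse) || nrow(abuse) == 0L) {
      sps[d] <- list(NULL)
      next
    }
    ref <- query_log |>
      dplyr::filter(norm_string(.data$query) == d) |>
      dplyr::transmute(period = .data$period, count = .data$count)
    sps[[d]] <- compute_sps(abuse, ref, suppress_share = suppress_share,
                            drug = d) |>
      cumulative_abuse_sps()
  }

  res <- correlate_domains(
    faers, sps,
    faers_series_kind = if (faers_series == "counts") {
      "quarterly co-report counts"
    } else {
      "quarterly ROR"
    }
  )
  if (!is.null(out)) {
    readr::write_csv(
      dplyr::select(tibble::as_tibble(res), "drug", "n", "rho", "p_two_sided",
                    "status", "faers_series_kind", "sps_series_kind"),
      out
    )
    return(invisible(res))
  }
  res
}

#' Simulate both domains and write the artifacts
#'
#' Writes `reports.csv` (report CSV dialect), `query_log.csv` (query-log
#' dialect) and `ground_truth.json` into `out_dir`, all deterministic under
#' the configuration seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
run_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  store <- simulate_reports(config)
  qlog <- simulate_query_log(config)
  gt <- ground_truth(config)

  paths <- c(
    reports = file.path(out_dir, "reports.csv"),
    query_log = file.path(out_dir, "query_log.csv"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  write_reports(store, paths[["reports"]])
  readr::write_csv(qlog, paths[["query_log"]])
  jsonlite::write_json(
    list(expected_or = gt$expected_or, expected_rho_sign = gt$expected_rho_sign),
    paths[["ground_truth"]], dataframe = "rows", digits = NA
  )
  invisible(paths)
}
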