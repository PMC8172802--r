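#' Default blocklist of non-abuse collocations
#'
#' Phrases that contain an abuse search term but are unrelated to abuse
#' (the classic case being "high blood pressure", which contains "high").
#' Queries matching any blocklist phrase are dropped by
#' [filter_abuse_queries()].
#'
#' @return Character vector of lowercase phrases.
#' @export
default_blocklist <- function() {
  c("high blood pressure", "high cholesterol")
}

#' Read a search-query log
#'
#' CSV with columns `query`, `period`, `count` and optionally `context_tag`
#' (the search-category restriction under which the log was collected, e.g.
#' `"prescription drug"`; it is carried as metadata, not re-derived).
#' Monthly `"YYYY-MM"` periods are aggregated to calendar quarters at
#' ingest; `aggregate` chooses the quarterly summary of monthly values.
#'
#' @param path CSV path.
#' @param aggregate `"mean"` (default) or `"sum"` for monthly-to-quarterly
#'   aggregation.
#' @return Tibble with columns `query`, `period` (`"YYYYQn"`), `count`
#'   (plus `context_tag` if present).
#' @export
read_query_log <- function(path, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (!file.exists(path)) abort(sprintf("Query log not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    query = readr::col_character(), period = readr::col_character(),
    count = readr::col_double(), .default = readr::col_character()
  ))
  aggregate_query_periods(raw, aggregate = aggregate)
}

#' @rdname read_query_log
#' @param records In-memory query records (columns `query`, `period`,
#'   `count`, ...).
#' @export
aggregate_query_periods <- function(records, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  records <- tibble::as_tibble(records)
  if (any(records$count < 0, na.rm = TRUE)) abort("Query counts must be non-negative.")
  fun <- if (aggregate == "mean") mean else sum
  records |>
    dplyr::mutate(query = norm_string(.data$query), period = as_quarter(.data$period)) |>
    dplyr::group_by(dplyr::across(-dplyr::all_of("count"))) |>
    dplyr::summarise(count = fun(.data$count), .groups = "drop")
}

#' Identify abuse-related queries for one drug
#'
#' Keeps the queries that mention the drug (generic or brand name) together
#' with at least one term of some abuse term set, and drops any query that
#' matches a blocklist collocation (e.g. "clonazepam and high blood
#' pressure", which mentions "high" but is unrelated to abuse).  A query
#' containing terms from several sets is tagged with each of them, so the
#' output can gain rows relative to the kept queries.  Matching is
#' whole-word on the normalized query string.
#'
#' @param records Query records (columns `query`, `period`, `count`).
#' @param drug Generic drug name resolved against `vocab`, or a
#'   `list(generic_name=, brand_names=)`.
#' @param term_sets Query term sets: a `vigicross_vocab`, its `query_terms`
#'   tibble, or `NULL` for the sets of `vocab`.
#' @param blocklist Phrases whose presence drops a query; default
#'   [default_blocklist()].
#' @param vocab A `vigicross_vocab` used to resolve `drug`/`term_sets`.
#' @return The kept records with an added `term_set` column; subset of the
#'   input rows (modulo multi-set tagging).
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   query = c("can you get high of pregabalin", "pregabalin dosage"),
#'   period = "2010Q1", count = c(10, 90)
#' )
#' filter_abuse_queries(recs, "pregabalin")$query
filter_abuse_queries <- function(records, drug, term_sets = NULL,
                                 blocklist = default_blocklist(),
                                 vocab = default_vocab()) {
  records <- tibble::as_tibble(records)
  d <- resolve_drug(drug, vocab)
  if (is.null(term_sets)) term_sets <- vocab$query_terms
  if (inherits(term_sets, "vigicross_vocab")) term_sets <- term_sets$query_terms

  q <- norm_string(records$query)
  names_rx <- word_regex(c(d$generic_name, d$brand_names))
  has_drug <- stringr::str_detect(q, names_rx)
  blocked <- Reduce(
    `|`,
    lapply(norm_string(blocklist), function(p) stringr::str_detect(q, stringr::fixed(p))),
    init = rep(FALSE, length(q))
  )

  tagged <- purrr::pmap_dfr(term_sets, function(name, search_terms, ...) {
    hit <- has_drug & !blocked & stringr::str_detect(q, word_regex(search_terms))
    dplyr::mutate(records[hit, ], term_set = name)
  })
  dplyr::arrange(tagged, .data$period, .data$query, .data$term_set)
}

# whole-word alternation regex over normalized phrases
word_regex <- function(phrases) {
  esc <- stringr::str_replace_all(norm_string(phrases), "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1")
  stringr::regex(paste0("\\b(", paste(esc, collapse = "|"), ")\\b"))
}

#' Search-popularity score (SPS) normalization
#'
#' Emulates the published normalization of search-interest data: within
#' each period the most popular related query (in this context, the plain
#' drug-name query) defines the scale, receiving a score of 100; any other
#' query scores `100 * volume / top-volume`, so a query searched half as
#' often as the top query scores 50.  Queries whose share of total related
#' searches in a period falls below `suppress_share` (default 1%) are not
#' reported: their score is set to 0 and flagged `suppressed`, mirroring
#' the big-data-only reporting of public search-analytics tools.  Periods
#' with no reference volume yield `NA` scores.
#'
#' @param records Tagged query records for one drug (columns `query`,
#'   `period`, `count`, `term_set`), typically from
#'   [filter_abuse_queries()].  Volumes are summed per period within each
#'   term set.
#' @param reference_counts Per-period volume of the top (drug-name) query:
#'   tibble with columns `period`, `count`.
#' @param related_totals Optional per-period total volume of all related
#'   searches (tibble `period`, `count`), the denominator of the
#'   suppression share.  Default: reference volume plus all record volumes
#'   in the period.
#' @param suppress_share Share below which a score is suppressed to 0;
#'   default `0.01`.
#' @param drug Optional drug label carried into the output.
#' @return Tibble with columns `drug`, `term_set`, `quarter`, `sps`,
#'   `suppressed`; per-term scores lie in `[0, 100]`.
#' @export
compute_sps <- function(records, reference_counts, related_totals = NULL,
                        suppress_share = 0.01, drug = NA_character_) {
  records <- tibble::as_tibble(records)
  if (!"term_set" %in% names(records)) records$term_set <- "all"
  reference_counts <- tibble::as_tibble(reference_counts) |>
    dplyr::mutate(period = as_quarter(.data$period)) |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(ref = sum(.data$count), .groups = "drop")

  vol <- records |>
    dplyr::mutate(period = as_quarter(.data$period)) |>
    dplyr::group_by(.data$term_set, .data$period) |>
    dplyr::summarise(volume = sum(.data$count), .groups = "drop") |>
    tidyr::complete(term_set = unique(records$term_set),
                    period = reference_counts$period,
                    fill = list(volume = 0))

  if (is.null(related_totals)) {
    related_totals <- vol |>
      dplyr::group_by(.data$period) |>
      dplyr::summarise(total = sum(.data$volume), .groups = "drop") |>
      dplyr::left_join(reference_counts, by = "period") |>
      dplyr::mutate(total = .data$total + dplyr::coalesce(.data$ref, 0)) |>
      dplyr::select("period", "total")
  } else {
    related_totals <- tibble::as_tibble(related_totals) |>
      dplyr::mutate(period = as_quarter(.data$period)) |>
      dplyr::group_by(.data$period) |>
      dplyr::summarise(total = sum(.data$count), .groups = "drop")
  }

  vol |>
    dplyr::left_join(reference_counts, by = "period") |>
    dplyr::left_join(related_totals, by = "period") |>
    dplyr::mutate(
      sps = dplyr::if_else(is.na(.data$ref) | .data$ref <= 0,
                           NA_real_, pmin(100, 100 * .data$volume / .data$ref)),
      share = dplyr::if_else(.data$total > 0, .data$volume / .data$total, 0),
      suppressed = !is.na(.data$sps) & .data$share < suppress_share,
      sps = dplyr::if_else(.data$suppressed, 0, .data$sps)
    ) |>
    dplyr::transmute(drug = drug, term_set = .data$term_set,
                     quarter = .data$period, sps = .data$sps,
                     suppressed = .data$suppressed) |>
    dplyr::arrange(.data$term_set, .data$quarter)
}

#' Cumulative abuse search interest over time
#'
#' Sums the per-term-set SPS values of one drug quarter by quarter.
#' Because each term set is normalized separately, the cumulative value may
#' legitimately exceed 100.  Suppressed components contribute exactly 0.
#' All series must cover the same quarters (and the same drug when
#' labelled), otherwise an error is raised.
#'
#' @param sps Tibble from [compute_sps()] (columns `term_set`, `quarter`,
#'   `sps`, ...), possibly several term sets.
#' @return Tibble with columns `quarter`, `sps` (one row per quarter).
#' @export
cumulative_abuse_sps <- function(sps) {
  sps <- tibble::as_tibble(sps)
  if ("drug" %in% names(sps) && dplyr::n_distinct(sps$drug, na.rm = TRUE) > 1) {
    abort("Cumulative SPS mixes several drugs.")
  }
  per_set <- split(sps$quarter, sps$term_set)
  if (length(per_set) > 1) {
    ref <- sort(per_set[[1]])
    same <- purrr::map_lgl(per_set, ~ identical(sort(.x), ref))
    if (!all(same)) abort("Window mismatch: term-set series cover different quarters.")
  }
  sps |>
    dplyr::group_by(.data$quarter) |>
    dplyr::summarise(sps = sum(.data$sps), .groups = "drop") |>
    dplyr::arrange(.data$quarter)
}

#' Summarize an SPS series
#'
#' Mean, median and interquartile range (linear-interpolation quantiles) of
#' the non-missing scores.  For a multi-term-set table, `by` chooses the
#' summary axis: `"overall"` pools everything, `"term_set"` summarizes each
#' set over quarters, `"quarter"` summarizes each quarter over sets --
#' published "average SPS" figures do not always state their axis, so all
#' three are available.
#'
#' @param sps A cumulative series (columns `quarter`, `sps`) or a
#'   [compute_sps()] table.
#' @param by `"overall"`, `"term_set"` or `"quarter"`.
#' @return Tibble with columns (`by` column,) `mean`, `median`, `q1`, `q3`,
#'   `n`.
#' @export
summarize_sps <- function(sps, by = c("overall", "term_set", "quarter")) {
  by <- match.arg(by)
  sps <- tibble::as_tibble(sps)
  vals <- sps[!is.na(sps$sps), ]
  if (nrow(vals) == 0L) abort("insufficient data: the series has no non-missing values.")
  grouped <- switch(by,
    overall = dplyr::mutate(vals, .group = "overall"),
    term_set = dplyr::mutate(vals, .group = .data$term_set),
    quarter = dplyr::mutate(vals, .group = .data$quarter)
  )
  out <- grouped |>
    dplyr::group_by(.data$.group) |>
    dplyr::summarise(
      mean = mean(.data$sps), median = median(.data$sps),
      q1 = quantile(.data$sps, 0.25, type = 7, names = FALSE),
      q3 = quantile(.data$sps, 0.75, type = 7, names = FALSE),
      n = dplyr::n(), .groups = "drop"
    )
  if (by == "overall") dplyr::select(out, -".group") else dplyr::rename(out, !!by := ".group")
}

#' Suppress a drug whose total search volume is too low
#'
#' Public search-analytics tools only report queries backed by large search
#' volumes; a drug whose total abuse-related query volume over the window
#' falls below the floor yields no series at all.  The floor is inclusive:
#' a volume exactly at `min_total_volume` is still reported.
#'
#' @param records Query records for one drug (column `count`).
#' @param min_total_volume Reporting floor on the summed volume.
#' @return `records` unchanged with attribute `insufficient_data = FALSE`,
#'   or an empty record tibble with `insufficient_data = TRUE`.
#' @seealso [insufficient_data()] to read the flag.
#' @export
apply_volume_floor <- function(records, min_total_volume) {
  check_number(min_total_volume, "min_total_volume", min = 0)
  records <- tibble::as_tibble(records)
  total <- sum(records$count, na.rm = TRUE)
  if (total < min_total_volume) {
    out <- records[0, ]
    attr(out, "insufficient_data") <- TRUE
  } else {
    out <- records
    attr(out, "insufficient_data") <- FALSE
  }
  out
}

#' @rdname apply_volume_floor
#' @param x An object returned by [apply_volume_floor()].
#' @export
insufficient_data <- function(x) {
  isTRUE(attr(x, "insufficient_data"))
}

#' Plot cumulative abuse-SPS timelines
#'
#' @param sps A cumulative series (columns `quarter`, `sps`), optionally
#'   with a `drug` column to colour by.
#' @return A ggplot object.
#' @export
plot_sps_timeline <- function(sps) {
  sps <- tibble::as_tibble(sps)
  sps$.t <- zoo::as.yearqtr(sps$quarter, format = "%YQ%q")
  aes <- if ("drug" %in% names(sps)) {
    ggplot2::aes(x = .data$.t, y = .data$sps, colour = .data$drug, group = .data$drug)
  } else {
    ggplot2::aes(x = .data$.t, y = .data$sps, group = 1)
  }
  ggplot2::ggplot(sps, aes) +
    ggplot2::geom_line() +
    zoo::scale_x_yearqtr(format = "%YQ%q") +
    ggplot2::labs(x = NULL, y = "Cumulative abuse-related SPS") +
    ggplot2::theme_minimal()
}
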