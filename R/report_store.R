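#' Build a cleaned store of spontaneous adverse-event reports
#'
#' A report store is the package's container for spontaneous-report
#' collections: one row per report with a report ID, a calendar quarter, a
#' set of drug names and a set of event preferred terms (PTs).  Construction
#' performs the cleaning steps a disproportionality analysis expects:
#' records with blank or missing drug/event sets are dropped, reports
#' outside the analysis window are dropped, reports sharing a `report_id`
#' are collapsed to the first occurrence, and (optionally) reports that are
#' content-identical on `(quarter, drugs, events)` under different IDs are
#' collapsed too.  Every removal is counted in a cleaning log.
#'
#' @param reports Tibble/data frame with columns `report_id`, `quarter`,
#'   `drugs`, `events`.  `drugs`/`events` may be list-columns of character
#'   vectors or semicolon-delimited strings.
#' @param window Inclusive quarter window `c(from, to)` as `"YYYYQn"`
#'   labels; defaults to the 54-quarter window 2007Q1--2020Q2.
#' @param dedupe_content Collapse content-identical reports with different
#'   IDs? Default `TRUE` (conservative; turn off for synthetic data where
#'   coincident reports are genuine).
#' @return A `report_store`: list with `reports` (tibble with list-columns
#'   `drugs`, `events`), `window`, and `log` (tibble of cleaning counts).
#' @export
#' @examples
#' rs <- report_store(tibble::tibble(
#'   report_id = c("r1", "r2"), quarter = c("2010Q1", "2010Q2"),
#'   drugs = c("Lyrica", "aspirin"), events = c("euphoric mood", "nausea")
#' ))
#' n_reports(rs)
report_store <- function(reports,
                         window = c("2007Q1", "2020Q2"),
                         dedupe_content = TRUE) {
  window <- check_window(window)
  reports <- tibble::as_tibble(reports)
  needed <- c("report_id", "quarter", "drugs", "events")
  missing_cols <- setdiff(needed, names(reports))
  if (length(missing_cols)) {
    abort(sprintf("Report data lacks column(s): %s.", paste(missing_cols, collapse = ", ")))
  }

  # flatten -> one vectorized normalization pass -> re-split (fast at 1e5+ rows)
  as_set_col <- function(col) {
    if (!is.list(col)) col <- stringr::str_split(as.character(col), ";")
    n <- length(col)
    flat <- norm_string(unlist(col, use.names = FALSE))
    idx <- rep.int(seq_len(n), lengths(col))
    keep <- !is.na(flat) & nzchar(flat) &
      !duplicated(paste0(idx, "\r", flat))
    flat <- flat[keep]
    idx <- idx[keep]
    ord <- order(idx, flat, method = "radix")
    unname(split(flat[ord], factor(idx[ord], levels = seq_len(n))))
  }

  log <- list()
  n0 <- nrow(reports)
  reports <- dplyr::mutate(
    reports,
    report_id = as.character(.data$report_id),
    quarter = as_quarter(.data$quarter),
    drugs = as_set_col(.data$drugs),
    events = as_set_col(.data$events)
  )

  blank <- lengths(reports$drugs) == 0L | lengths(reports$events) == 0L |
    is.na(reports$report_id) | !nzchar(reports$report_id) | is.na(reports$quarter)
  log$blank_fields <- sum(blank)
  reports <- reports[!blank, ]

  in_window <- reports$quarter %in% quarter_seq(window[1], window[2])
  log$outside_window <- sum(!in_window)
  reports <- reports[in_window, ]

  dup_id <- duplicated(reports$report_id)
  log$duplicate_id <- sum(dup_id)
  reports <- reports[!dup_id, ]

  if (dedupe_content) {
    key <- paste(reports$quarter,
                 purrr::map_chr(reports$drugs, paste, collapse = ";"),
                 purrr::map_chr(reports$events, paste, collapse = ";"),
                 sep = "\r")
    dup_content <- duplicated(key)
    log$duplicate_content <- sum(dup_content)
    reports <- reports[!dup_content, ]
  } else {
    log$duplicate_content <- 0L
  }

  structure(
    list(
      reports = reports[, needed],
      window = window,
      log = tibble::tibble(step = names(log), n_removed = unlist(log, use.names = FALSE),
                           n_input = n0)
    ),
    class = "report_store"
  )
}

#' @export
print.report_store <- function(x, ...) {
  cat(sprintf("<report_store: %d reports, window %s..%s, %d removed in cleaning>\n",
              nrow(x$reports), x$window[1], x$window[2], sum(x$log$n_removed)))
  invisible(x)
}

#' @rdname report_store
#' @param store A `report_store`.
#' @return `n_reports()`: the number of reports (the grand total N).
#' @export
n_reports <- function(store) {
  stopifnot(inherits(store, "report_store"))
  nrow(store$reports)
}

#' Read spontaneous reports from CSV or JSON lines
#'
#' The CSV dialect has header columns `report_id, quarter, drugs, events`
#' with semicolon-delimited drug/event cells (UTF-8).  The JSON-lines
#' alternative has one object per line with the same fields, list-valued.
#' Returns the raw tibble; pass it to [report_store()] for cleaning.
#'
#' @param path Path to a `.csv` or `.jsonl`/`.ndjson` file.
#' @return Tibble with columns `report_id`, `quarter`, `drugs`, `events`.
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) abort(sprintf("Report file not found: %s", path))
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(stringr::str_squish(lines))]
    recs <- purrr::map(lines, jsonlite::fromJSON)
    tibble::tibble(
      report_id = purrr::map_chr(recs, ~ as.character(.x$report_id)),
      quarter = purrr::map_chr(recs, ~ as.character(.x$quarter)),
      drugs = purrr::map(recs, ~ as.character(unlist(.x$drugs))),
      events = purrr::map(recs, ~ as.character(unlist(.x$events)))
    )
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  }
}

#' Write a report store in the package's CSV dialect
#'
#' @param store A `report_store`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(store, path) {
  stopifnot(inherits(store, "report_store"))
  out <- dplyr::mutate(
    store$reports,
    drugs = purrr::map_chr(.data$drugs, paste, collapse = ";"),
    events = purrr::map_chr(.data$events, paste, collapse = ";")
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Normalize drug names to generics
#'
#' Every drug string matching a brand name in the vocabulary
#' (case-insensitively) is replaced by its generic name; unrecognized names
#' are case-folded and kept.  Because drug mentions are sets, a report
#' naming the same drug under both brand and generic collapses to a single
#' mention.
#'
#' @param x A `report_store`, or a tibble with a `drugs` list-column.
#' @param vocab A `vigicross_vocab` (default [default_vocab()]).
#' @return Object of the same type as `x` with normalized `drugs`.
#' @export
#' @examples
#' tb <- tibble::tibble(drugs = list(c("LYRICA", "pregabalin")))
#' normalize_drug_names(tb)$drugs[[1]] # "pregabalin"
normalize_drug_names <- function(x, vocab = default_vocab()) {
  stopifnot(inherits(vocab, "vigicross_vocab"))
  brand_map <- vocab$drugs |>
    dplyr::mutate(brand = .data$brand_names) |>
    tidyr::unnest_longer("brand")
  lookup <- setNames(brand_map$generic_name, brand_map$brand)

  fix <- function(d) {
    d <- norm_string(d)
    hit <- d %in% names(lookup)
    d[hit] <- lookup[d[hit]]
    sort(unique(d))
  }

  if (inherits(x, "report_store")) {
    x$reports$drugs <- purrr::map(x$reports$drugs, fix)
    x
  } else {
    x <- tibble::as_tibble(x)
    x$drugs <- purrr::map(x$drugs, fix)
    x
  }
}

# vectorized: which rows of a list-column contain any of `values`
member_flags <- function(col, values) {
  n <- length(col)
  flat <- unlist(col, use.names = FALSE)
  idx <- rep.int(seq_len(n), lengths(col))
  out <- logical(n)
  out[idx[flat %in% values]] <- TRUE
  out
}

# logical vectors: which reports mention the drug / any PT of the category
store_flags <- function(store, drug, category, vocab) {
  d <- resolve_drug(drug, vocab)
  cat_ <- resolve_category(category, vocab)
  list(drug = d, category = cat_,
       has_drug = member_flags(store$reports$drugs, d$generic_name),
       has_evt = member_flags(store$reports$events, cat_$pt_list))
}

#' Count the 2x2 marginals for one drug and one term category
#'
#' Builds the contingency table of the disproportionality analysis: `a` =
#' reports mentioning the drug and at least one PT of the category, `b` =
#' drug without the category, `c` = category without the drug, `d` =
#' neither.  The comparator is thus "all other drugs and all other events"
#' in the same store, and `a + b + c + d` equals the store's grand total.
#'
#' @param store A `report_store` (drug names already normalized to
#'   generics; see [normalize_drug_names()]).
#' @param drug Generic drug name present in `vocab` (or a
#'   `list(generic_name=, brand_names=)`).  An unknown drug is an error; a
#'   known drug absent from the store yields `a = b = 0`.
#' @param category Category name in `vocab`, or a `list(name=, pt_list=)`.
#' @param vocab A `vigicross_vocab`.
#' @return A [contingency_table()] with attributes `drug` and `category`.
#' @export
count_marginals <- function(store, drug, category, vocab = default_vocab()) {
  stopifnot(inherits(store, "report_store"))
  if (n_reports(store) == 0L) abort("The report store is empty.")
  fl <- store_flags(store, drug, category, vocab)
  a <- sum(fl$has_drug & fl$has_evt)
  b <- sum(fl$has_drug & !fl$has_evt)
  c_ <- sum(!fl$has_drug & fl$has_evt)
  d <- sum(!fl$has_drug & !fl$has_evt)
  tab <- contingency_table(a, b, c_, d)
  attr(tab, "drug") <- fl$drug$generic_name
  attr(tab, "category") <- fl$category$name
  tab
}

#' Quarterly co-report counts for one drug and one term category
#'
#' One value per quarter of the store window (zero-filled where the quarter
#' has no qualifying reports); the value is the number of reports mentioning
#' both the drug and the category in that quarter.  Summed over the window
#' this equals the `a` cell of [count_marginals()].
#'
#' @inheritParams count_marginals
#' @return Tibble with columns `quarter`, `n`, one row per window quarter.
#' @export
quarterly_counts <- function(store, drug, category, vocab = default_vocab()) {
  stopifnot(inherits(store, "report_store"))
  fl <- store_flags(store, drug, category, vocab)
  quarters <- quarter_seq(store$window[1], store$window[2])
  hits <- store$reports$quarter[fl$has_drug & fl$has_evt]
  counts <- table(factor(hits, levels = quarters))
  tibble::tibble(quarter = quarters, n = as.integer(counts))
}
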