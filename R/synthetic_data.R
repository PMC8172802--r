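#' Configuration for the two-domain synthetic generator
#'
#' Defines a joint generating model for both surveillance domains with
#' closed-form ground truth.  Report side: each quarter produces
#' `n_reports_per_quarter` reports; a report mentions each study drug
#' independently with its marginal probability (plus one background filler
#' drug so the comparator cells are populated), and mentions each event
#' category with a probability whose *odds* are `background odds x
#' latent_trend(quarter) x enrichment(drug, category)` for the drugs
#' present.  Because enrichment acts on the odds scale, the large-sample
#' reporting odds ratio of a pair equals its configured enrichment exactly.
#' Search side: each quarter each drug gets a top drug-name query with
#' `query_volume` searches and one abuse query per term set with volume
#' `query_volume x abuse_share x weight x latent_trend^coupling x noise`,
#' plus decoy queries (a blocklist collocation and a non-abuse query) to
#' exercise filtering.  `coupling` in [-1, 1] interpolates between a fully
#' shared temporal trend (+1, or -1 for an inverted trend) and independent
#' lognormal noise (0); the expected sign of the cross-domain Spearman
#' correlation is the sign of `coupling`.
#'
#' Default marginal probabilities are the published FAERS-wide fractions of
#' the four study drugs and five categories (e.g. 107,905 / 7,430,750 for
#' pregabalin), default enrichments are the published RORs (illustrative
#' defaults, not re-derivations), and default abuse shares mirror the
#' published average search-interest levels, with levetiracetam's query
#' volume set low enough to fall under typical reporting floors.
#'
#' @param seed Integer RNG seed; a fixed seed makes both generators
#'   byte-identical across runs.
#' @param window Inclusive quarter window (default 2007Q1--2020Q2).
#' @param n_reports_per_quarter Reports per quarter (default 2500).
#' @param drug_prob Named per-drug mention probabilities.
#' @param category_prob Named per-category background event probabilities;
#'   names must be categories of `vocab`.
#' @param enrichment Tibble `drug`, `category`, `or` of odds multipliers
#'   (pairs not listed have enrichment 1); `NULL` for the published-ROR
#'   defaults over the default drugs/categories.
#' @param latent_trend Numeric vector, one multiplier per window quarter
#'   (positive); `NULL` for a gentle linear rise from 0.6 to 1.4.
#' @param query_volume Named per-drug baseline volume of the top query.
#' @param abuse_share Named per-drug fraction of abuse-related query volume
#'   relative to the top query.
#' @param coupling Cross-domain coupling in [-1, 1] (default 1).
#' @param query_noise_sd Lognormal sd of the abuse-query noise at coupling
#'   0 (scaled by `1 - |coupling|`); default 0.3.
#' @param vocab Vocabulary supplying category PT lists and query term sets.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       window = c("2007Q1", "2020Q2"),
                       n_reports_per_quarter = 2500L,
                       drug_prob = c(pregabalin = 0.01452, gabapentin = 0.01378,
                                     levetiracetam = 0.00590, clonazepam = 0.00752),
                       category_prob = c(drug_abuse_and_dependence = 0.01601,
                                         drug_withdrawal = 0.00379,
                                         overdose = 0.01148,
                                         tolerance = 0.000264,
                                         euphoria = 0.03770),
                       enrichment = NULL,
                       latent_trend = NULL,
                       query_volume = c(pregabalin = 800, gabapentin = 1600,
                                        levetiracetam = 40, clonazepam = 3200),
                       abuse_share = c(pregabalin = 0.1125, gabapentin = 0.225,
                                       levetiracetam = 0.08, clonazepam = 0.455),
                       coupling = 1,
                       query_noise_sd = 0.3,
                       vocab = default_vocab()) {
  check_number(seed, "seed")
  window <- check_window(window)
  nq <- length(quarter_seq(window[1], window[2]))
  check_number(n_reports_per_quarter, "n_reports_per_quarter", min = 1)
  stopifnot(inherits(vocab, "vigicross_vocab"))

  check_probs <- function(p, what) {
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      abort(sprintf("`%s` must be a named vector.", what))
    }
    if (any(p < 0 | p > 1)) abort(sprintf("`%s` values must lie in [0, 1].", what))
    p
  }
  drug_prob <- check_probs(drug_prob, "drug_prob")
  category_prob <- check_probs(category_prob, "category_prob")
  unknown_cat <- setdiff(names(category_prob), vocab$categories$name)
  if (length(unknown_cat)) {
    abort(sprintf("category_prob names not in the vocabulary: %s.",
                  paste(unknown_cat, collapse = ", ")))
  }

  if (is.null(enrichment)) {
    enrichment <- default_enrichment()
  }
  enrichment <- tibble::as_tibble(enrichment)
  stopifnot(all(c("drug", "category", "or") %in% names(enrichment)))
  if (any(enrichment$or <= 0)) abort("Enrichment odds multipliers must be positive.")
  enrichment <- dplyr::filter(enrichment,
                              .data$drug %in% names(drug_prob),
                              .data$category %in% names(category_prob))

  if (is.null(latent_trend)) latent_trend <- seq(0.6, 1.4, length.out = nq)
  if (length(latent_trend) != nq) {
    abort(sprintf("latent_trend must have one value per window quarter (%d).", nq))
  }
  if (any(latent_trend <= 0)) abort("latent_trend multipliers must be positive.")

  if (!is.numeric(coupling) || abs(coupling) > 1) abort("`coupling` must lie in [-1, 1].")
  check_number(query_noise_sd, "query_noise_sd", min = 0)
  check_probs(abuse_share, "abuse_share")
  if (any(query_volume < 0)) abort("query_volume must be non-negative.")

  structure(
    list(seed = as.integer(seed), window = window,
         n_reports_per_quarter = as.integer(n_reports_per_quarter),
         drug_prob = drug_prob, category_prob = category_prob,
         enrichment = enrichment, latent_trend = latent_trend,
         query_volume = query_volume, abuse_share = abuse_share,
         coupling = coupling, query_noise_sd = query_noise_sd, vocab = vocab),
    class = "sim_config"
  )
}

# illustrative defaults: the published screen's RORs as enrichment multipliers
default_enrichment <- function() {
  m <- faers_marginals()
  screen <- ror_screen(m)
  tibble::tibble(drug = screen$drug, category = screen$category, or = screen$ror)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config: seed %d, %s..%s, %d reports/quarter, %d drugs, %d categories, coupling %g>\n",
    x$seed, x$window[1], x$window[2], x$n_reports_per_quarter,
    length(x$drug_prob), length(x$category_prob), x$coupling
  ))
  invisible(x)
}

# deterministic RNG setup shared by both generators
seed_rng <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

# background pools so b/c/d cells and non-study queries are populated
filler_drugs <- function() {
  c("aspirin", "metformin", "lisinopril", "atorvastatin", "omeprazole",
    "amlodipine", "metoprolol", "albuterol", "sertraline", "ibuprofen",
    "levothyroxine", "azithromycin", "amoxicillin", "hydrochlorothiazide",
    "simvastatin", "losartan", "furosemide", "prednisone", "tramadol",
    "warfarin")
}

filler_events <- function() {
  c("nausea", "headache", "fatigue", "rash", "vomiting", "diarrhoea",
    "pruritus", "pyrexia", "insomnia", "constipation", "dyspnoea", "cough",
    "arthralgia", "myalgia", "anaemia", "hypertension", "oedema peripheral",
    "somnolence", "tremor", "palpitations", "abdominal pain", "asthenia",
    "dry mouth", "weight increased", "weight decreased", "anxiety",
    "depression", "blurred vision", "tinnitus", "back pain")
}

#' Generate a synthetic spontaneous-report store
#'
#' Draws reports under the model of [sim_config()].  Every report carries
#' one background filler drug and one filler event in addition to any study
#' drugs/category PTs, so all four cells of every 2x2 table are populated.
#' Content-level deduplication is off in the returned store: at synthetic
#' scale distinct reports legitimately coincide on (quarter, drugs, events).
#'
#' @param config A [sim_config()].
#' @return A [report_store()].
#' @export
#' @examples
#' st <- simulate_reports(sim_config(seed = 7, window = c("2010Q1", "2010Q4"),
#'                                   n_reports_per_quarter = 200))
#' n_reports(st)
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed_rng(config$seed)
  quarters <- quarter_seq(config$window[1], config$window[2])
  nq <- length(quarters)
  npq <- config$n_reports_per_quarter
  m <- nq * npq
  q_idx <- rep(seq_len(nq), each = npq)
  log_trend <- log(config$latent_trend)[q_idx]

  drug_names <- names(config$drug_prob)
  has_drug <- vapply(drug_names,
                     function(d) rbinom(m, 1L, config$drug_prob[[d]]) == 1L,
                     logical(m))
  if (m == 1L) has_drug <- matrix(has_drug, nrow = 1)

  # long-format mention lists, starting with the always-present fillers
  drug_idx <- seq_len(m)
  drug_val <- sample(filler_drugs(), m, replace = TRUE)
  evt_idx <- seq_len(m)
  evt_val <- sample(filler_events(), m, replace = TRUE)

  for (j in seq_along(drug_names)) {
    hit <- which(has_drug[, j])
    drug_idx <- c(drug_idx, hit)
    drug_val <- c(drug_val, rep(drug_names[j], length(hit)))
  }

  cats <- config$vocab$categories
  for (cat_name in names(config$category_prob)) {
    p0 <- config$category_prob[[cat_name]]
    lo <- log(p0 / (1 - p0)) + log_trend
    for (j in seq_along(drug_names)) {
      enr <- config$enrichment$or[config$enrichment$drug == drug_names[j] &
                                    config$enrichment$category == cat_name]
      if (length(enr) == 1 && enr != 1) lo <- lo + has_drug[, j] * log(enr)
    }
    present <- which(rbinom(m, 1L, plogis(lo)) == 1L)
    if (length(present)) {
      pts <- cats$pt_list[[match(cat_name, cats$name)]]
      evt_idx <- c(evt_idx, present)
      evt_val <- c(evt_val, sample(pts, length(present), replace = TRUE))
    }
  }

  reports <- tibble::tibble(
    report_id = sprintf("SIM%07d", seq_len(m)),
    quarter = quarters[q_idx],
    drugs = unname(split(drug_val, factor(drug_idx, levels = seq_len(m)))),
    events = unname(split(evt_val, factor(evt_idx, levels = seq_len(m))))
  )
  report_store(reports, window = config$window, dedupe_content = FALSE)
}

#' Generate a synthetic search-query log
#'
#' One top drug-name query per drug per quarter at the configured baseline
#' volume, one abuse query per term set (templated, e.g. "can you get high
#' of pregabalin") whose volume follows the shared latent trend to the
#' degree set by `coupling`, and two decoy queries per drug per quarter --
#' one matching a blocklist collocation ("... and high blood pressure") and
#' one with no abuse term ("... dosage") -- so downstream filtering is
#' exercised.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `query`, `period`, `count`, `context_tag`.
#' @export
simulate_query_log <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed_rng(bitwXor(config$seed, 77231L))
  quarters <- quarter_seq(config$window[1], config$window[2])
  nq <- length(quarters)
  term_sets <- config$vocab$query_terms
  sd_eff <- config$query_noise_sd * (1 - abs(config$coupling))
  w <- 1 / nrow(term_sets)

  per_drug <- purrr::map(names(config$query_volume), function(d) {
    vol <- config$query_volume[[d]]
    share <- unname(config$abuse_share[d])
    if (is.na(share)) share <- 0
    top <- tibble::tibble(query = d, period = quarters, count = vol)
    abuse <- purrr::pmap_dfr(term_sets, function(name, search_terms, ...) {
      term <- search_terms[[1]]
      qstr <- if (term == "high") {
        sprintf("can you get high of %s", d)
      } else {
        sprintf("%s %s", d, term)
      }
      noise <- exp(rnorm(nq, 0, sd_eff))
      tibble::tibble(
        query = qstr, period = quarters,
        count = vol * share * w * config$latent_trend^config$coupling * noise
      )
    })
    decoys <- tibble::tibble(
      query = rep(c(sprintf("%s and high blood pressure", d), sprintf("%s dosage", d)),
                  times = nq),
      period = rep(quarters, each = 2),
      count = rep(c(0.08, 0.30) * vol, times = nq)
    )
    dplyr::bind_rows(top, abuse, decoys)
  })

  dplyr::bind_rows(per_drug) |>
    dplyr::mutate(context_tag = "prescription drug") |>
    dplyr::arrange(.data$period, .data$query)
}

#' Closed-form ground truth of a simulation configuration
#'
#' The expected large-sample reporting odds ratio of every drug x category
#' pair equals its configured enrichment multiplier (1 where none is
#' configured), and the expected sign of the cross-domain Spearman
#' correlation per drug is the sign of `coupling` (0 for drugs generating
#' no abuse-query volume).  Both are derivable from the configuration
#' alone, without simulating.
#'
#' @param config A [sim_config()].
#' @return List with `expected_or` (tibble `drug`, `category`, `or`) and
#'   `expected_rho_sign` (tibble `drug`, `sign`).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  expected_or <- tidyr::expand_grid(
    drug = names(config$drug_prob),
    category = names(config$category_prob)
  ) |>
    dplyr::left_join(config$enrichment, by = c("drug", "category")) |>
    dplyr::mutate(or = dplyr::coalesce(.data$or, 1))
  share_vec <- config$abuse_share[names(config$query_volume)]
  share_vec[is.na(share_vec)] <- 0
  expected_rho_sign <- tibble::tibble(
    drug = names(config$query_volume),
    sign = ifelse(share_vec > 0 & config$query_volume > 0, sign(config$coupling), 0)
  )
  list(expected_or = expected_or, expected_rho_sign = expected_rho_sign)
}
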