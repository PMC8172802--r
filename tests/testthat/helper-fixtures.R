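# Shared fixtures and scenario configurations, all built in code.

# four reports covering each cell of the drug x event 2x2 exactly once
toy_store <- function() {
  report_store(tibble::tibble(
    report_id = c("r1", "r2", "r3", "r4"),
    quarter = "2010Q1",
    drugs = list("pregabalin", "pregabalin", "aspirin", "aspirin"),
    events = list("euphoric mood", "nausea", "euphoric mood", "nausea")
  ))
}

# small random report tibble for oracle comparisons
random_reports <- function(n, seed, quarters = c("2009Q1", "2009Q2", "2009Q3")) {
  set.seed(seed)
  all_drugs <- c("pregabalin", "gabapentin", "aspirin", "metformin", "ibuprofen")
  all_events <- c("euphoric mood", "dizziness", "overdose", "nausea", "headache", "rash")
  tibble::tibble(
    report_id = sprintf("r%05d", seq_len(n)),
    quarter = sample(quarters, n, replace = TRUE),
    drugs = replicate(n, sample(all_drugs, sample(1:3, 1)), simplify = FALSE),
    events = replicate(n, sample(all_events, sample(1:3, 1)), simplify = FALSE)
  )
}

# naive per-report double loop over the store: the counting oracle
brute_marginals <- function(store, drug, pt_set) {
  a <- b <- c_ <- d <- 0L
  for (i in seq_len(nrow(store$reports))) {
    has_drug <- drug %in% store$reports$drugs[[i]]
    has_evt <- FALSE
    for (ev in store$reports$events[[i]]) {
      if (ev %in% pt_set) has_evt <- TRUE
    }
    if (has_drug && has_evt) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_evt) c_ <- c_ + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c_, d = d)
}

# ROR parameter-recovery scenario: 200,000 reports, configured odds ratio 3
recovery_config <- function(seed) {
  sim_config(
    seed = seed, window = c("2007Q1", "2007Q4"), n_reports_per_quarter = 50000L,
    drug_prob = c(pregabalin = 0.0145),
    category_prob = c(drug_abuse_and_dependence = 0.016),
    enrichment = tibble::tibble(drug = "pregabalin",
                                category = "drug_abuse_and_dependence", or = 3),
    query_volume = c(pregabalin = 800), abuse_share = c(pregabalin = 0.11)
  )
}

# null screen scenario: study-scale probabilities, no enrichment anywhere
null_config <- function(seed, n_per_quarter = 500L) {
  sim_config(
    seed = seed, n_reports_per_quarter = n_per_quarter,
    enrichment = tibble::tibble(drug = character(), category = character(),
                                or = numeric())
  )
}

# cross-domain power scenario: drug-focused extract, strong shared trend
power_config <- function(seed, coupling) {
  sim_config(
    seed = seed, n_reports_per_quarter = 600L,
    drug_prob = c(pregabalin = 0.3),
    category_prob = c(drug_abuse_and_dependence = 0.016),
    enrichment = tibble::tibble(drug = "pregabalin",
                                category = "drug_abuse_and_dependence", or = 3),
    latent_trend = seq(0.4, 2.0, length.out = 54),
    query_volume = c(pregabalin = 2000), abuse_share = c(pregabalin = 0.2),
    coupling = coupling
  )
}
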