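test_that("abuse-query filtering keeps, tags and drops as documented", {
  recs <- tibble::tibble(
    query = c("can you get high of pregabalin", "pregabalin and high blood pressure",
              "pregabalin dosage", "pregabalin abuse overdose", "lyrica withdrawal",
              "gabapentin abuse"),
    period = "2010Q1",
    count = c(10, 20, 90, 5, 7, 30)
  )
  out <- filter_abuse_queries(recs, "pregabalin")
  expect_true(all(out$query %in% recs$query)) # pure filter
  expect_true("can you get high of pregabalin" %in% out$query)
  expect_identical(out$term_set[out$query == "can you get high of pregabalin"], "euphoria")
  expect_false("pregabalin and high blood pressure" %in% out$query) # blocklist
  expect_false("pregabalin dosage" %in% out$query)                  # no abuse term
  expect_false("gabapentin abuse" %in% out$query)                   # other drug
  # a query with terms from two sets is tagged with both
  expect_setequal(out$term_set[out$query == "pregabalin abuse overdose"],
                  c("drug_abuse_and_dependence", "overdose"))
  # brand names count as drug mentions
  expect_true("lyrica withdrawal" %in% out$query)
})

test_that("SPS normalizes against the top query and suppresses sub-1% shares", {
  recs <- tibble::tibble(query = "q", period = c("2010Q1", "2010Q2"),
                         count = c(100, 200), term_set = "euphoria")
  ref <- tibble::tibble(period = c("2010Q1", "2010Q2"), count = c(200, 200))
  sps <- compute_sps(recs, ref, related_totals = ref)
  expect_equal(sps$sps, c(50, 100))
  expect_false(any(sps$suppressed))

  # 5 / 1000 = 0.5% of related searches: reported as 0 and flagged
  low <- compute_sps(
    tibble::tibble(query = "q", period = "2010Q1", count = 5, term_set = "euphoria"),
    tibble::tibble(period = "2010Q1", count = 1000),
    related_totals = tibble::tibble(period = "2010Q1", count = 1000)
  )
  expect_identical(low$sps, 0)
  expect_true(low$suppressed)

  # a period with no reference volume yields a missing score, not an error
  no_ref <- compute_sps(
    tibble::tibble(query = "q", period = "2010Q1", count = 5, term_set = "x"),
    tibble::tibble(period = "2010Q1", count = 0)
  )
  expect_true(is.na(no_ref$sps))
})

test_that("SPS is scale invariant and per-term scores stay within [0, 100]", {
  set.seed(77)
  for (i in 1:10) {
    n_q <- 6
    periods <- quarter_seq("2010Q1", "2011Q2")
    recs <- tibble::tibble(
      query = "q", period = rep(periods, 2),
      count = stats::runif(2 * n_q, 0, 800),
      term_set = rep(c("s1", "s2"), each = n_q)
    )
    ref <- tibble::tibble(period = periods, count = stats::runif(n_q, 500, 1000))
    base <- compute_sps(recs, ref)
    expect_true(all(base$sps >= 0 & base$sps <= 100, na.rm = TRUE))
    k <- stats::runif(1, 0.1, 50)
    scaled <- compute_sps(dplyr::mutate(recs, count = count * k),
                          dplyr::mutate(ref, count = count * k))
    expect_equal(scaled$sps, base$sps)
    expect_identical(scaled$suppressed, base$suppressed)
  }
})

test_that("cumulative SPS adds term sets, may exceed 100, and checks windows", {
  two <- tibble::tibble(term_set = c("a", "b"), quarter = "2010Q1",
                        sps = c(30, 40), suppressed = FALSE)
  expect_equal(cumulative_abuse_sps(two)$sps, 70)

  five <- tibble::tibble(term_set = letters[1:5], quarter = "2010Q1",
                         sps = 25, suppressed = FALSE)
  expect_equal(cumulative_abuse_sps(five)$sps, 125) # legitimately above 100

  all_sup <- tibble::tibble(term_set = c("a", "b"), quarter = "2010Q1",
                            sps = 0, suppressed = TRUE)
  expect_equal(cumulative_abuse_sps(all_sup)$sps, 0)

  mismatch <- tibble::tibble(term_set = c("a", "b"), quarter = c("2010Q1", "2010Q2"),
                             sps = 1, suppressed = FALSE)
  expect_error(cumulative_abuse_sps(mismatch), "Window mismatch")

  # cumulative never falls below its largest component
  set.seed(5)
  periods <- quarter_seq("2012Q1", "2012Q4")
  tbl <- tidyr::expand_grid(term_set = c("a", "b", "c"), quarter = periods) |>
    dplyr::mutate(sps = stats::runif(dplyr::n(), 0, 100), suppressed = FALSE)
  cum <- cumulative_abuse_sps(tbl)
  max_comp <- tapply(tbl$sps, tbl$quarter, max)
  expect_true(all(cum$sps >= max_comp[cum$quarter]))
})

test_that("SPS summaries use interpolated quantiles and reject empty series", {
  const <- tibble::tibble(quarter = quarter_seq("2010Q1", "2011Q4"), sps = 10)
  s <- summarize_sps(const)
  expect_equal(c(s$mean, s$median, s$q1, s$q3), c(10, 10, 10, 10))

  four <- tibble::tibble(quarter = quarter_seq("2010Q1", "2010Q4"), sps = 1:4)
  expect_equal(summarize_sps(four)$median, 2.5)

  empty <- tibble::tibble(quarter = "2010Q1", sps = NA_real_)
  expect_error(summarize_sps(empty), "insufficient data")

  by_set <- tibble::tibble(term_set = rep(c("a", "b"), each = 2),
                           quarter = rep(c("2010Q1", "2010Q2"), 2),
                           sps = c(1, 3, 10, 30))
  out <- summarize_sps(by_set, by = "term_set")
  expect_equal(out$mean[out$term_set == "b"], 20)
})

test_that("generator-fed SPS matches its configured mean search interest", {
  # coupling 1 makes the search side deterministic: cumulative SPS equals
  # 100 * abuse_share * trend, so its mean over the window is 100 * share
  cfg <- sim_config(seed = 3, coupling = 1)
  ql <- simulate_query_log(cfg)
  abuse <- filter_abuse_queries(ql, "clonazepam")
  ref <- dplyr::filter(ql, query == "clonazepam")[, c("period", "count")]
  cum <- cumulative_abuse_sps(compute_sps(abuse, ref, drug = "clonazepam"))
  expect_equal(summarize_sps(cum)$mean, 45.5, tolerance = 0.001)
})

test_that("the volume floor suppresses low-search-volume drugs inclusively", {
  recs <- tibble::tibble(query = "q", period = "2010Q1", count = c(3, 4))
  at_floor <- apply_volume_floor(recs, 7)
  expect_false(insufficient_data(at_floor)) # inclusive threshold
  expect_identical(nrow(at_floor), 2L)

  below <- apply_volume_floor(recs, 7.5)
  expect_true(insufficient_data(below))
  expect_identical(nrow(below), 0L)

  none <- apply_volume_floor(recs[0, ], 1)
  expect_true(insufficient_data(none))
})
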