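test_that("table_from_marginals forces the cells and rejects inconsistent counts", {
  tab <- table_from_marginals(7430750, 107905, 118980, 4558)
  expect_identical(c(tab$a, tab$b, tab$c, tab$d),
                   c(4558, 103347, 114422, 7208423))
  expect_identical(tab$n, 7430750)

  degenerate <- table_from_marginals(10, 5, 5, 5)
  expect_identical(c(degenerate$a, degenerate$b, degenerate$c, degenerate$d),
                   c(5, 0, 0, 5))

  expect_error(table_from_marginals(100, 20, 30, 40), "n_drug")
  expect_error(table_from_marginals(100, 40, 30, 35), "n_category")
  expect_error(table_from_marginals(40, 30, 30, 5), "n_total")
})

test_that("compute_ror reproduces known tables and the balanced case", {
  r <- compute_ror(table_from_marginals(7430750, 107905, 118980, 4558))
  expect_identical(report_round(c(r$ror, r$ci_low, r$ci_high)), c(2.78, 2.70, 2.86))
  expect_true(r$is_signal)

  r2 <- compute_ror(contingency_table(98, 55758, 1867, 7373027))
  expect_identical(report_round(c(r2$ror, r2$ci_low, r2$ci_high)), c(6.94, 5.66, 8.51))

  bal <- compute_ror(contingency_table(10, 10, 10, 10))
  expect_equal(bal$ror, 1)
  expect_equal(log(bal$ci_low), -log(bal$ci_high)) # symmetric about 1 on log scale
})

test_that("zero cells follow the documented contract", {
  expect_error(compute_ror(contingency_table(5, 0, 3, 10)), "undefined ROR")
  expect_error(compute_ror(contingency_table(5, 3, 0, 10)), "undefined ROR")

  corrected <- compute_ror(contingency_table(5, 0, 3, 10), correction = TRUE)
  expect_true(is.finite(corrected$ror) && corrected$ror > 0)

  zero_a <- compute_ror(contingency_table(0, 4, 6, 20))
  expect_identical(zero_a$ror, 0)
  expect_false(zero_a$ci_available)
  expect_false(zero_a$is_signal) # no co-reports can never signal

  # d = 0 also zeroes the cross product: the estimate collapses, CI withheld
  zero_d <- compute_ror(contingency_table(3, 4, 6, 0))
  expect_identical(zero_d$ror, 0)
  expect_false(zero_d$ci_available)
  expect_false(zero_d$is_signal)
})

test_that("ROR symmetries and CI behaviour hold over random tables", {
  set.seed(42)
  for (i in 1:25) {
    cells <- sample(1:500, 4, replace = TRUE)
    r <- compute_ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    # transposing the drug/event roles (b <-> c) leaves the ROR unchanged
    t_swap <- compute_ror(contingency_table(cells[1], cells[3], cells[2], cells[4]))
    expect_equal(t_swap$ror, r$ror)
    # swapping which column is the event (a <-> b, c <-> d) inverts it
    recip <- compute_ror(contingency_table(cells[2], cells[1], cells[4], cells[3]))
    expect_equal(recip$ror, 1 / r$ror)
    # quadrupling every cell keeps the ROR, narrows the interval
    scaled <- compute_ror(contingency_table(4 * cells[1], 4 * cells[2],
                                            4 * cells[3], 4 * cells[4]))
    expect_equal(scaled$ror, r$ror)
    expect_lt(log(scaled$ci_high) - log(scaled$ci_low),
              log(r$ci_high) - log(r$ci_low))
  }
})

test_that("the signal criterion uses strict thresholds", {
  expect_false(detect_signal(n_combination = 3, ci_low = 5))   # exactly 3 co-reports
  expect_true(detect_signal(n_combination = 4, ci_low = 1.001))
  expect_false(detect_signal(n_combination = 100, ci_low = 1)) # bound exactly 1
  expect_true(detect_signal(compute_ror(table_from_marginals(7430750, 107905,
                                                             118980, 4558))))
  expect_error(detect_signal(compute_ror(contingency_table(0, 4, 6, 20))),
               "confidence interval")
})

test_that("ror_screen runs from marginals and from a store, consistently", {
  m <- faers_marginals()
  screen <- ror_screen(m)
  expect_s3_class(screen, "ror_screen")
  expect_identical(nrow(screen), 20L)
  one <- ror_screen(m[m$drug == "pregabalin" & m$category == "euphoria", ])
  direct <- compute_ror(table_from_marginals(7430750, 107905, 280097, 10664))
  expect_equal(one$ror, direct$ror)

  st <- report_store(random_reports(500, seed = 13))
  from_store <- ror_screen(st, drugs = "pregabalin", categories = "euphoria",
                           correction = TRUE)
  tab <- count_marginals(st, "pregabalin", "euphoria")
  expect_equal(from_store$ror,
               compute_ror(tab, correction = TRUE)$ror)

  g <- glance(screen)
  expect_identical(g$n_pairs, 20L)
  td <- tidy(screen)
  expect_true(all(c("estimate", "conf.low", "conf.high") %in% names(td)))
  expect_s3_class(autoplot(screen), "ggplot")
})

test_that("quarterly ROR series conserves co-reports and flags undefined quarters", {
  raw <- random_reports(400, seed = 31)
  st <- report_store(raw)
  qs <- quarterly_ror(st, "pregabalin", "euphoria")
  expect_identical(qs$quarter, quarter_seq("2007Q1", "2020Q2"))
  agg <- count_marginals(st, "pregabalin", "euphoria")
  expect_identical(sum(qs$n_combination), as.numeric(agg$a))
  # quarters with no reports at all are missing, not errors
  expect_true(all(is.na(qs$ror[!qs$quarter %in% c("2009Q1", "2009Q2", "2009Q3")])))

  # a store confined to one quarter reproduces the aggregate in that quarter
  one_q <- report_store(random_reports(200, seed = 5, quarters = "2012Q3"))
  qs1 <- quarterly_ror(one_q, "pregabalin", "euphoria")
  agg1 <- compute_ror(count_marginals(one_q, "pregabalin", "euphoria"))
  expect_equal(qs1$ror[qs1$quarter == "2012Q3"], agg1$ror)
  expect_identical(sum(!is.na(qs1$ror)), 1L)
})

test_that("report_round reproduces display rounding of published screens", {
  expect_identical(report_round(c(4.2847, 2.4049, 1.0949, 2.2447)),
                   c(4.29, 2.41, 1.10, 2.25))
  expect_identical(report_round(2.78499), 2.79)
  expect_identical(round_half_up(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
})
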