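test_that("brand names normalize to generics with set semantics", {
  tb <- tibble::tibble(drugs = list("Lyrica", "pregabalin", c("LYRICA", "pregabalin"),
                                    c("Keppra", "Tylenol")))
  out <- normalize_drug_names(tb)$drugs
  expect_identical(out[[1]], "pregabalin")
  expect_identical(out[[2]], "pregabalin")
  expect_identical(out[[3]], "pregabalin") # brand + generic collapse to one mention
  expect_identical(out[[4]], c("levetiracetam", "tylenol")) # unknowns case-folded, kept
})

test_that("cleaning drops duplicates, blanks and out-of-window reports with a log", {
  raw <- tibble::tibble(
    report_id = c("a", "a", "b", "c", "d", "e"),
    quarter = c("2010Q1", "2010Q1", "2010Q1", "2010Q1", "2003Q1", "2010Q2"),
    drugs = c("pregabalin", "gabapentin", "pregabalin", "pregabalin", "aspirin", ""),
    events = c("nausea", "nausea", "nausea", "nausea", "rash", "rash")
  )
  st <- report_store(raw)
  # kept: first "a" and one of the content-identical {a, b, c} family
  expect_identical(n_reports(st), 1L)
  log <- setNames(st$log$n_removed, st$log$step)
  expect_identical(log[["duplicate_id"]], 1L)
  expect_identical(log[["duplicate_content"]], 2L)
  expect_identical(log[["outside_window"]], 1L)
  expect_identical(log[["blank_fields"]], 1L)

  # content collapse is toggleable
  st2 <- report_store(raw, dedupe_content = FALSE)
  expect_identical(n_reports(st2), 3L)

  # empty input gives an empty store
  expect_identical(n_reports(report_store(raw[0, ])), 0L)
})

test_that("deduplication is idempotent", {
  raw <- random_reports(120, seed = 3)
  raw$report_id[5] <- raw$report_id[4]
  once <- report_store(raw)
  twice <- report_store(once$reports)
  expect_identical(twice$reports, once$reports)
  expect_identical(sum(twice$log$n_removed), 0L)
})

test_that("count_marginals matches the exhaustive four-cell toy and errors on unknown drugs", {
  tab <- count_marginals(toy_store(), "pregabalin", "euphoria")
  expect_identical(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))
  expect_identical(attr(tab, "drug"), "pregabalin")

  # a vocabulary drug absent from the store: a = b = 0, no error
  tab2 <- count_marginals(toy_store(), "clonazepam", "euphoria")
  expect_identical(c(tab2$a, tab2$b), c(0, 0))
  expect_identical(tab2$n, 4)

  expect_error(count_marginals(toy_store(), "quetiapine", "euphoria"), "quetiapine")
  expect_error(count_marginals(report_store(random_reports(5, 1)[0, ]),
                               "pregabalin", "euphoria"), "empty")
})

test_that("count_marginals agrees with the naive double loop on random stores", {
  v <- default_vocab()
  for (seed in c(7, 8)) {
    st <- report_store(random_reports(300, seed = seed))
    for (pair in list(c("pregabalin", "euphoria"), c("gabapentin", "overdose"))) {
      tab <- count_marginals(st, pair[1], pair[2], v)
      pts <- v$categories$pt_list[[match(pair[2], v$categories$name)]]
      oracle <- brute_marginals(st, pair[1], pts)
      expect_identical(c(tab$a, tab$b, tab$c, tab$d), unname(as.numeric(oracle)))
      expect_identical(tab$n, as.numeric(n_reports(st))) # conservation
    }
  }
})

test_that("quarterly counts cover the window, zero-fill and conserve the a cell", {
  st <- report_store(random_reports(400, seed = 21))
  qc <- quarterly_counts(st, "pregabalin", "euphoria")
  expect_identical(qc$quarter, quarter_seq("2007Q1", "2020Q2"))
  expect_length(qc$n, 54)
  tab <- count_marginals(st, "pregabalin", "euphoria")
  expect_identical(sum(qc$n), as.integer(tab$a))
  # all activity is confined to three 2009 quarters in this fixture
  expect_true(all(qc$n[!qc$quarter %in% c("2009Q1", "2009Q2", "2009Q3")] == 0L))
})

test_that("report files round-trip through the CSV and JSONL dialects", {
  st <- report_store(random_reports(40, seed = 9))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_reports(st, csv)
  back <- report_store(read_reports(csv))
  expect_identical(back$reports$drugs, st$reports$drugs)
  expect_identical(back$reports$events, st$reports$events)

  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"report_id":"x1","quarter":"2010Q1","drugs":["Lyrica"],"events":["euphoric mood"]}',
    '{"report_id":"x2","quarter":"2010Q2","drugs":["aspirin","ibuprofen"],"events":["rash"]}'
  ), jl)
  tb <- read_reports(jl)
  expect_identical(tb$drugs[[2]], c("aspirin", "ibuprofen"))
  expect_identical(n_reports(report_store(tb)), 2L)
})
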