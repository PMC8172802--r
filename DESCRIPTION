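Package: vigicross
Title: Cross-Domain Drug-Abuse Safety Signals from Spontaneous Reports
    and Search Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting drug-abuse safety signals by combining two
    surveillance domains: disproportionality analysis of spontaneous
    adverse-event reports (reporting odds ratios with Woolf confidence
    intervals and a co-report/confidence-bound signal criterion) and
    search-engine infoveillance (search-popularity-score timelines for
    abuse-related queries).  Includes MedDRA-style term-category and
    drug-name vocabularies, report cleaning and quarterly indexing,
    Spearman rank correlation between the two quarterly domains, a
    seeded synthetic-data generator with closed-form ground truth for
    both domains, and a packaged fixture of published FAERS marginal
    counts (2007-2020Q2) for four anticonvulsant and benzodiazepine
    drugs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml,
    zoo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
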