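---
title: "Detecting drug-abuse safety signals across spontaneous reports and search analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting drug-abuse safety signals across spontaneous reports and search analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigicross)
library(dplyr)
```

## The problem

Gabapentinoids (pregabalin, gabapentin) are widely prescribed GABA-derivative
anticonvulsants whose recreational misuse has become a pharmacovigilance
concern. vigicross implements a two-domain surveillance methodology for such
abuse signals: a **report domain** — disproportionality analysis of a
spontaneous adverse-event reporting database such as FAERS — and a **search
domain** — timelines of abuse-related query popularity from a public search
engine — joined by a rank correlation of the two quarterly series. The
package ships the aggregate marginal counts of a published 2007Q1–2020Q2
FAERS screen of the two gabapentinoids against a positive control with
well-established abuse liability (clonazepam) and a negative control
(levetiracetam), so the full screen is reproducible on a laptop without any
report-level data.

## The report domain: reporting odds ratios

For one drug and one event-term category, reports are cross-classified into
the 2×2 table (a = drug and category co-reported, b = drug only, c =
category only, d = neither; the comparator is all other drugs and all other
events in the same database). The reporting odds ratio is

$$\mathrm{ROR} = \frac{a\,d}{b\,c},$$

with the Woolf log-normal interval
$\exp\!\left(\ln \mathrm{ROR} \pm z\sqrt{1/a + 1/b + 1/c + 1/d}\right)$.
A pair is a *safety signal* when the co-report count is **greater than 3**
and the CI lower bound is **greater than 1**, both strict. Defaults follow
the published convention: `z = 1.96`, no continuity correction (all
published cells are positive; a Haldane–Anscombe 0.5 is available behind
`correction = TRUE` for zero cells, in which case the correction is applied
to all four cells of the affected table only).

Three numerical conventions matter when comparing with published tables:

* **Interval method.** The publication does not state its CI method; the
  Woolf interval is the package's choice because it reproduces every
  published bound at display precision.
* **Display rounding.** `report_round()` rounds half-up through a
  one-extra-digit intermediate (4.2847 → 4.285 → 4.29), matching how the
  upstream analysis tool displays estimates. Four of the sixty published
  numbers differ from plain rounding precisely by this convention. Internal
  computation is always full precision.
* **Degenerate cells.** `b = 0` or `c = 0` leaves the ROR undefined (error
  unless corrected); `a = 0` or `d = 0` collapses the cross product to a
  zero estimate, which is returned with its CI flagged unavailable and can
  never be a signal.

Event terms are grouped into MedDRA-style categories. The two narrow-scope
SMQ categories ship with *placeholder* PT lists because SMQ membership is
licensed MedDRA content; users holding a license should override them.
Analyses driven by published marginal counts are unaffected by the
placeholders. Term matching is exact after case-folding and whitespace
normalization — published category definitions are literal PT lists, so no
stemming or fuzzy matching is attempted.

Report cleaning mirrors standard practice: ID-level deduplication always;
content-level deduplication of reports identical on (quarter, drugs,
events) on by default but toggleable, since the upstream tool's exact
algorithm is unpublished and a conservative, reproducible rule was
preferred; all removals are counted in a cleaning log. Reports are indexed
by calendar quarter ("YYYYQn", window inclusive at both ends; the default
window 2007Q1–2020Q2 spans 54 quarters). A drug named under both brand and
generic in one report counts once (set semantics).

## The search domain: search-popularity scores

Public search-analytics tools report a *search-popularity score* (SPS) on a
0–100 scale: the most popular related query (here always the plain
drug-name query) scores 100 and any other query scores proportionally, so a
query searched half as often as the top query scores 50. Queries with a
search share below 1% of related searches are not reported and appear as 0;
the package flags these as suppressed. Per-term scores therefore live in
[0, 100], while the *cumulative* abuse timeline — the sum over term sets —
may legitimately exceed 100. The true ranking internals of the search
engine are closed; the package implements this operational contract as its
emulation target, which also gives scale invariance: multiplying all raw
volumes in a period by a constant changes no score.

Abuse queries are identified lexically: a query is kept when it contains
the drug's generic or a brand name and at least one term of an abuse term
set ("high" standing in for euphoria, which lacks search volume), and
dropped when it matches a blocklist collocation such as "high blood
pressure" — the programmatic counterpart of the manual curation a human
analyst applies. Monthly records are aggregated to quarters at ingest
(arithmetic mean by default, sum optionally). A drug whose total
abuse-query volume falls below a reporting floor yields no series but an
explicit "insufficient data" flag (inclusive threshold: a volume exactly at
the floor is reported) — the behaviour a low-interest drug such as
levetiracetam shows in practice.

Because published "average SPS" figures do not state their averaging axis,
`summarize_sps()` reports mean/median/IQR over the pooled values, per term
set, or per quarter, as requested.

## Joining the domains

Per drug, the quarterly co-report counts of the primary category (or,
optionally, quarterly RORs) are aligned with the quarterly cumulative
abuse-SPS series on their common complete quarters; dropped quarters are
logged. Association is measured by Spearman's rank correlation — only
monotonicity, not linearity, is assumed between two such different data
generating processes — with the two-sided p-value from the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, standard at
the ~54-quarter series lengths involved. An exact permutation p-value is
available for very short series; the cutoff is n ≤ 8, where full
enumeration (8! orderings) is instantaneous — beyond that the enumeration
cost grows factorially while adding nothing at the lengths this method
analyses. A perfect rho of ±1 reports the smallest positive double rather
than zero. Fewer than three paired quarters is an error ("insufficient
overlap"); drugs in that position surface as "insufficient data" rows in
`run_correlation()` rather than as failures.

Published correlation figures for this methodology depend on proprietary,
non-archived search data, so the correlation stage is validated three ways
instead: oracle equivalence (hand-computed tied ranks, exact permutation
enumeration, and `stats::cor.test` as an independent cross-check),
consistency of published (r, p) pairs via `pvalue_from_rho()` under the
54-quarter window, and parameter recovery on synthetic data.

## The synthetic generator

`sim_config()` defines a joint generating model for both domains with
closed-form ground truth:

* **Reports.** Each quarter yields a fixed number of reports; study-drug
  mentions are independent Bernoulli draws; every report carries one
  background filler drug and one filler event so all four table cells are
  populated. Event-category presence has odds `background odds ×
  latent_trend(quarter) × enrichment(drug, category)` for drugs present.
  Enrichment acts on the *odds* scale precisely so that the configured
  multiplier equals the large-sample ROR — ground truth without
  simulation.
* **Queries.** Per drug and quarter: a top drug-name query at baseline
  volume, one templated abuse query per term set with volume `baseline ×
  abuse_share × latent_trend^coupling × noise`, and two decoy queries (a
  blocklist collocation and a no-abuse-term query) to exercise filtering.
  `coupling` in [−1, 1] interpolates between a fully shared temporal trend
  and independent lognormal noise (the noise sd scales with 1 − |coupling|),
  so the expected sign of the cross-domain correlation is `sign(coupling)`.

Defaults are anchored to the published study conditions: drug and category
probabilities are the published FAERS-wide marginal fractions (e.g.
107,905 / 7,430,750 for pregabalin), enrichments default to the published
RORs (illustrative, not re-derivations), abuse shares mirror the published
average search-interest levels (0.455 for clonazepam, hence a mean
cumulative SPS of 45.5 under a unit-mean trend), and levetiracetam's query
volume sits below typical reporting floors. The default latent trend is a
gentle linear rise (0.6 → 1.4, unit mean) standing in for the secular
growth both real domains show. The generator makes no attempt to model
reporting demographics, stimulated reporting waves, or search seasonality;
passing tests therefore demonstrate correctness of the statistical
machinery under a known monotone-trend model, not fidelity to every
feature of real surveillance streams. Both generators are byte-identical
under a fixed seed.

## Validation problem sizes

The test suite validates the stochastic claims at sizes chosen to keep a
full run comfortable on a single CPU: ROR parameter recovery uses 50
replicates of 200,000 reports (4 quarters × 50,000) with enrichment 3.0,
checking 95%-interval coverage of the truth in at least 90% of seeds; null
calibration screens 50 replicates of the default study probabilities at
500 reports/quarter over the full window (27,000 reports), expecting the
signal rule to fire for at most 10% of drug–category pairs; correlation
power uses a drug-focused extract (mention probability 0.30, 600
reports/quarter, trend 0.4 → 2.0, coupling 1) where the coupled
correlation must be positive with p < 0.05 in at least 95% of 50 seeds,
with the uncoupled configuration rejecting in at most 10%.

## Known limitations

Disproportionality quantifies reporting asymmetry, not risk, and no
causal reading of either domain or of their correlation is supported.
Exact reproduction of report-level FAERS counts is impossible without the
licensed SMQ term lists; the packaged marginal counts are the
reproducible anchor. The search domain is an emulation of a closed
system's documented behaviour. The whole-word lexical query filter does
not attempt semantic classification of queries, and quarters with
suppressed search scores enter the correlation as zeros unless the
caller drops them.
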