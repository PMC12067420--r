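---
title: "Disproportionality signal detection and time-to-onset analysis"
author: "pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and time-to-onset analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous-report databases such as FAERS (US) and JADER (Japan) collect
adverse drug event (ADE) reports from clinicians, manufacturers and
consumers. They have no denominator — nobody knows how many patients took a
drug uneventfully — so drug safety questions are asked *relatively*: is
event `e` reported with drug `d` more often than it is reported with all
other drugs? This package implements the standard screening pipeline for
that question on FAERS/JADER-shaped data: deduplication, target-drug case
selection, 2×2 contingency tables, four disproportionality algorithms with
Bonferroni correction, and Weibull time-to-onset analysis, together with a
fully seeded synthetic-report generator used to validate every stage
against known ground truth.

## Ingestion and deduplication

FAERS cases accumulate *versions*: the same CASEID reappears across
quarterly files under new PRIMARYIDs. Following the standard cleaning
rules, `deduplicate()` keeps, per CASEID, the row with the most recent
FDA_DT, breaking ties by the larger PRIMARYID (the more recently submitted
report); rows whose FDA_DT is not a parseable 8-digit date are excluded and
counted. `apply_deletions()` then removes any case whose CASEID appears on
the quarterly deleted-report list. On synthetic data with injected
duplicate versions and deletions, the recovered survivor set is checked to
equal the generator's recorded ground truth exactly.

Because neither database uses harmonized drug coding, a target drug is a
*synonym set* (`drug_query()`), e.g. the pirfenidone set includes both
trade names and the Japanese generic name. Matching is exact on the
case-folded, trimmed name — no substring matching, which avoids false
captures at the price of requiring explicit name lists. By default only
primary-suspect (PS) drug rows qualify a case; `exclude_concomitant()`
provides the monotherapy sensitivity analysis (cases with zero distinct
non-target drug names).

Events are counted as **distinct (case, PT) pairs**: a preferred term
repeated within one case counts once. The databases do not dictate this
unit; per-case uniqueness was chosen because it is invariant to report
versioning and prevents double counting. At system-organ-class level a case
likewise counts once per SOC however many of its PTs map there, which can
only reduce counts relative to summing member PTs — SOC totals then read as
case counts. PTs with fewer than `min_count = 3` occurrences in the target
case set are kept in listings but excluded from signal analysis.

Outcome codes need one decision: the published demographic tables report
outcome blocks that sum exactly to the report total, implying one outcome
per case, so `select_drug_cases()` keeps the single most serious code per
case in the order DE > LT > HO > DS > CA > RI > OT, with `Missing` when no
outcome row exists. Ages are decoded from their unit codes (years, months,
days, weeks, decades) before banding; anything unparseable is `Unknown`.
Percentages are rounded half-up to one decimal, the convention of the
published tables.

## The four algorithms

All four operate on the 2×2 table for one drug and one term, with cells
`a` (target drug, target event), `b` (target drug, other events), `c`
(other drugs, target event), `d` (neither), `n = a+b+c+d`, and the
independence expectation `E = (a+b)(a+c)/n`.

**ROR** — reporting odds ratio `(ad)/(bc)` with the log-scale Wald 95%
interval `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`. Undefined when `bc = 0`.

**PRR** — proportional reporting ratio `[a/(a+b)]/[c/(c+d)]` with the
Pearson chi-squared statistic `n(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]` on 1 df.
The uncorrected statistic is the default (a `yates` switch exists because
part of the literature uses the continuity-corrected form); `c = 0` makes
the ratio denominator vanish and the term not evaluable.

**BCPNN** — the information component
`IC = log2 P(d,e)/(P(d)P(e))` in the original closed-form posterior-moment
formulation with the conventional priors (cell weight 1, marginal weights
1, overall weights 2, joint weight tuned so E(IC) = 0 under independence).
`ic` is E(IC) and `ic025 = E(IC) − 2√V(IC)`, the moment-based lower bound.

**MGPS** — empirical Bayes gamma-Poisson shrinkage. The true reporting
ratio λ carries a two-component gamma mixture prior; marginally the count
`a` is a mixture of negative binomials, and `fit_gps_prior()` maximizes
that marginal likelihood over all of a drug's tables by log-parameterized
bounded quasi-Newton (L-BFGS-B) from five fixed starting points including
the conventional `(0.2, 0.1, 2, 4, 1/3)`. The posterior is again a gamma
mixture; `EBGM = 2^{E[log2 λ | a]}` and `EBGM05` is the posterior 5th
percentile, obtained by bisection on the mixture CDF to 1e−8 (verified in
the tests against numerical quadrature of the posterior built from
scratch). Within `run_pipeline()` one prior is fitted per drug on the PT
tables — the richer collection — and shared with the SOC level, where five
tables would be far too few for a stable empirical-Bayes fit.

**Positivity** uses the standard published cut-offs, all strict: ROR
requires `a ≥ 3` and CI lower bound > 1; PRR requires PRR ≥ 2, χ² ≥ 4 and
`a ≥ 3`; BCPNN requires IC025 > 0; MGPS requires EBGM05 > 2. A term is a
signal only when **all four** agree — the conjunction trades sensitivity
for a low false-positive rate, which is what the all-null synthetic runs
measure. Chi-squared p-values are Bonferroni-corrected,
`P-adj = min(1, P·n)` with `n` the number of evaluable terms for that drug
and level, and declared significant below 0.05. Bonferroni is the only
multiplicity procedure offered. The volcano table reports `log2(ROR)`
against `−log10(P-adj)`.

## Time to onset

TTO is `EVENT_DT − START_DT` in calendar days, the interval from therapy
start (THER file; the earliest start among the target drug's therapy rows)
to event onset (DEMO file; in the JADER layout both dates travel on the
DRUG rows). Missing dates, partial dates (YYYYMM or shorter — excluded
rather than imputed, the strict reading of "inaccurate or missing data"),
and negative intervals are excluded, and the tallies satisfy
`n_input = n_used + n_missing + n_partial + n_negative` for every sample.

Summaries report the median and quartiles (type-7 linear interpolation, so
IQRs are reproducible) and counts over eight onset-period bins — (0–30],
(30–60], (60–90], (90–120], (120–180], (180–360], (360–720], >720 days;
the exact boundaries are a documented, configurable choice, and day-0
events fall in the first bin. Histogram percentages carry two decimals so
they sum to 100 within rounding noise.

`fit_weibull()` estimates scale α (days) and shape β by maximum likelihood
on log parameters, with 95% intervals from the observed-information normal
approximation — adequate at the sample sizes involved; profile likelihood
is not attempted. Day-0 events are kept at 0 in medians and histograms but
moved to 0.5 days for the likelihood (the Weibull support is t > 0); both
the substitute value and the bins are configurable. The failure type reads
off the shape interval: **early** (β < 1, CI upper < 1, risk declining),
**random** (CI contains 1), **wear-out** (β > 1, CI lower > 1, risk
rising). Between-group onset comparisons use the Kruskal–Wallis rank test
with tie correction; a fully tied sample (0/0 tie correction) is reported
as H = 0, p = 1.

## The synthetic generator

`generate_reports()` emulates the features of quarterly extracts that the
pipeline consumes: one DEMO row per report version; exactly one
primary-suspect DRUG row per case, plus concomitant (role C) rows with
configurable probability (default 0.3) so the sensitivity filter has work
to do; 1 + Poisson(2) preferred terms per report, mirroring multi-PT
reports (the real multiplicity is not published; this is a modelling
choice); drug-event sampling probability proportional to
`background weight × RR(d, e)`, so planted pairs are over-reported by a
known relative risk; Weibull onset intervals per drug (default scale 100
days, shape 0.7 — the early-failure regime reported for the antifibrotic
drugs this pipeline was built around); 8-digit YYYYMMDD dates with a
configurable fraction of event dates emitted blank or truncated to YYYYMM
(default 0.2) to exercise the exclusion logic; and duplicate case versions
(default 10%) plus a deleted-case list (default 5%) whose intended
survivors are recorded as ground truth. Identical seeds give byte-identical
files.

What the generator does *not* emulate — narrative text, real MedDRA
hierarchy below PT→SOC, reporting-rate secular trends, correlated
drug-event confounding — bounds what passing tests show: they demonstrate
that the pipeline's algorithms and bookkeeping are correct, not that any
particular real-world signal is causal.

## Numerical and design notes

* Problem sizes in the tests and the acceptance script were chosen as the
  smallest that make the statistical checks sharp: 20,000 reports for
  planted-signal and null-calibration runs, 10,000 pairs for prior
  recovery, 5,000 draws for Weibull shape recovery, 2,000 cases for dedup
  recovery.
* The published headline signal tables of any real FAERS study depend on
  the full background counts of the database, which are not part of any
  paper's text; they are therefore validated here structurally (oracle
  equivalence, planted-signal recovery, null calibration) rather than
  numerically.
* `fit_gps_prior()` can legitimately drive one mixture component to a very
  concentrated gamma when the data contain a single strong signal among
  many null pairs; bounds on the log parameters (±12) keep the optimum
  finite, and the posterior summaries remain well defined.
* Degenerate inputs fail loudly: single-drug datasets (no background),
  empty synonym sets, all-equal onset samples, expected counts of zero.

## Limitations

Disproportionality is a screening statistic, not an effect estimate: it
inherits all reporting biases of spontaneous systems (stimulated
reporting, indication confounding, missing denominators), and a positive
four-way signal is a hypothesis for pharmacoepidemiologic follow-up, not
evidence of causation. The pipeline's indication-PT exclusion list is
configurable precisely because indications masquerading as events are the
most common artifact; the default list is each drug's reported
indications.
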