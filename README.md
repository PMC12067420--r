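# pvsignal

Disproportionality signal detection and time-to-onset analysis for
spontaneous adverse-event reports.

## What this is for

Spontaneous-report pharmacovigilance databases — FAERS (quarterly
`$`-delimited DEMO/DRUG/REAC/OUTC/THER/INDI tables plus a deleted-case
list) and JADER (DEMO/DRUG/REAC/HIST) — have no exposure denominator, so
post-marketing safety questions are asked relatively: is event *e*
reported with drug *d* disproportionately often against the
all-other-drugs background? `pvsignal` implements the full screening
pipeline used by such studies:

1. **Ingestion & deduplication** — per CASEID keep the most recent FDA_DT,
   ties broken by the higher PRIMARYID; drop cases on the deleted-report
   list; select target-drug cases by an explicit synonym set (no
   harmonized drug coding exists) restricted to primary-suspect (PS) role
   rows; map preferred terms (PT) to system organ classes (SOC); drop PTs
   with fewer than 3 occurrences.
2. **Contingency tables** — for each term the 2×2 cells
   (`a`, `b`, `c`, `d`) counting distinct (case, term) pairs, with the
   independence expectation `E = (a+b)(a+c)/n`.
3. **Four disproportionality algorithms** —
   ROR `= ad/bc` with its Wald 95% CI;
   PRR `= [a/(a+b)]/[c/(c+d)]` with the Pearson χ² (1 df);
   the BCPNN information component `IC = log2 P(d,e)/(P(d)P(e))` with
   closed-form Bayesian shrinkage, reported as E(IC) and
   `IC025 = E(IC) − 2√V(IC)`;
   and the empirical-Bayes gamma-Poisson shrinker,
   `EBGM = 2^{E[log2 λ | a]}` under a fitted two-component gamma-mixture
   prior on the reporting ratio λ, with EBGM05 its posterior 5th
   percentile. A term is a **positive signal only when all four agree**
   (ROR lower CI > 1 with a ≥ 3; PRR ≥ 2 with χ² ≥ 4; IC025 > 0;
   EBGM05 > 2), and χ² p-values carry a Bonferroni correction
   `P-adj = min(1, P·n)`.
4. **Time to onset** — days from therapy start (START_DT) to event onset
   (EVENT_DT), with missing/partial/negative intervals excluded and
   tallied; medians and quartiles, 8-period histograms, a maximum-
   likelihood Weibull fit (scale α, shape β), and the failure-type call:
   early (β < 1, CI < 1, declining risk), random (CI spans 1), wear-out
   (β > 1, CI > 1). Kruskal–Wallis rank tests compare onset across terms.
5. **Synthetic ground truth** — a seeded generator produces
   FAERS/JADER-shaped tables with planted relative risks, duplicate case
   versions, deleted cases and Weibull onset intervals, so every stage is
   validated against known truth without the multi-gigabyte public dumps.

## Worked example

Plant one drug-event pair with relative risk 20 in 20,000 synthetic
reports and run the whole pipeline for that drug:

```r
library(pvsignal)
cfg <- synth_config(n_drugs = 6, n_events = 200, n_reports = 20000,
                    planted_pairs = data.frame(drug = 2, event = 17, rr = 20),
                    seed = 2025)
res <- run_pipeline(pv_config("synthetic", synth = cfg,
                              drugs = list(drug_query("DRUG_02"))))
s <- res$drugs$DRUG_02$signals_pt
head(s[order(-s$positive, -s$a), ], 3)
```

```
    term   a    ror   ror_l    prr      chi2   ic025  ebgm ebgm05 p_adj positive
1 PT_017 784 19.285 16.6307 17.699 2881.8336  2.1235 4.826 4.8063     0     TRUE
2 PT_002  56  1.175  0.8785  1.174    1.1818 -0.2334 0.930 0.9261     1    FALSE
3 PT_128  55  1.158  0.8642  1.157    0.9682 -0.2531 0.930 0.9261     1    FALSE
```

The planted pair (and only it) is positive by all four algorithms: its ROR
of 19.3 estimates the planted relative risk of 20, the information
component lower bound 2.12 bits and the shrunk EBGM05 of 4.8 clear their
thresholds, and the Bonferroni-adjusted p rounds to 0. The onset analysis
of the same drug recovers the generator's Weibull regime (scale 100 days,
shape 0.7):

```r
res$drugs$DRUG_02$weibull
#> <weibull_fit> n = 2517: scale 105.3 (99.3-111.6) days,
#>               shape 0.704 (0.683-0.725), early failure type
```

A shape below 1 with its whole interval below 1 is the early-failure
pattern: adverse-event risk concentrated at the start of therapy and
declining thereafter.

File-based workflows use `read_faers_quarter()` / `read_jader()` with a
PT→SOC map (`read_term_map()`), and `inst/scripts/pv-pipeline.R` is a thin
command-line wrapper over the same functions.

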