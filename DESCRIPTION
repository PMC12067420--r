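Package: pvsignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for post-marketing pharmacovigilance analysis of
    spontaneous adverse event reports shaped like the public FAERS and JADER
    quarterly extracts: report-level deduplication and deleted-case handling,
    drug-of-interest case selection by synonym lists and primary-suspect role
    codes, preferred-term to system-organ-class mapping, four
    disproportionality algorithms (reporting odds ratio, proportional
    reporting ratio with chi-squared test, the Bayesian confidence propagation
    neural network information component, and the multi-item gamma Poisson
    shrinker empirical Bayes geometric mean) with Bonferroni correction,
    Weibull time-to-onset modelling with failure-type classification, and a
    synthetic-data generator with planted relative risks for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
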