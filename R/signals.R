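# Frequentist disproportionality statistics (ROR, PRR + chi-squared), the
# BCPNN information component, Bonferroni correction, four-way positivity,
# and plot-ready tables.

#' Reporting odds ratio with 95% Wald interval
#'
#' `ROR = (a d)/(b c)`, interval
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When `b c = 0` the
#' ratio is undefined (`NA`, not evaluable); when `a = 0` (with `b c > 0`)
#' the ROR is 0 with an undefined interval.
#'
#' @param a,b,c,d cell counts (vectorized).
#' @return data.frame with columns `ror`, `ror_l`, `ror_u`.
#' @export
ror_stat <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  ror <- (a * d) / (b * c)
  ror[rep_len(b * c == 0, length(ror))] <- NA_real_
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ok <- !is.na(ror) & ror > 0 & is.finite(se)
  l <- u <- rep(NA_real_, length(a))
  l[ok] <- exp(log(ror[ok]) - 1.96 * se[ok])
  u[ok] <- exp(log(ror[ok]) + 1.96 * se[ok])
  df0(ror = ror, ror_l = l, ror_u = u)
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the accompanying statistic is the Pearson
#' chi-squared on the 2x2 table, `n (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`
#' (optionally Yates-corrected), with the p-value from the chi-squared
#' distribution with 1 df. With `c = 0` the ratio denominator vanishes and
#' the calculation cannot be performed (`NA`).
#'
#' @param a,b,c,d cell counts (vectorized).
#' @param yates apply the continuity correction (default FALSE).
#' @return data.frame with columns `prr`, `chi2`, `p_raw`.
#' @export
prr_stat <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  prr <- (a / (a + b)) / (c / (c + d))
  prr[rep_len(c == 0 | a + b == 0, length(prr))] <- NA_real_
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(num - n / 2, 0)
  chi2 <- n * num^2 / denom
  chi2[rep_len(denom == 0, length(chi2))] <- NA_real_
  df0(prr = prr, chi2 = chi2,
      p_raw = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' BCPNN information component (closed-form posterior moments)
#'
#' The information component `IC = log2[P(drug, event) / (P(drug) P(event))]`
#' with Bayesian shrinkage, in the original closed-form posterior-moment
#' formulation: conventional priors give cell weight `gamma11 = 1`, marginal
#' weights `alpha1 = beta1 = 1` and overall weights `alpha = beta = 2`, with
#' the joint prior weight `gamma` tuned so the expectation vanishes under
#' independence. The reported `ic` is E(IC); `ic025 = E(IC) - 2 sqrt(V(IC))`
#' is the conventional lower bound from the posterior variance.
#'
#' @param a,b,c,d cell counts (vectorized).
#' @return data.frame with columns `ic`, `ic025`, `ic_var`.
#' @export
bcpnn_stat <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n11 <- a
  n1. <- a + b
  n.1 <- a + c
  alpha1 <- 1; beta1 <- 1; alpha <- 2; beta <- 2; gamma11 <- 1
  gamma <- gamma11 * (n + alpha) * (n + beta) /
    ((n1. + alpha1) * (n.1 + beta1))
  e_ic <- log2((n11 + gamma11) * (n + alpha) * (n + beta) /
                 ((n + gamma) * (n1. + alpha1) * (n.1 + beta1)))
  v_ic <- (1 / log(2)^2) *
    ((n - n11 + gamma - gamma11) / ((n11 + gamma11) * (1 + n + gamma)) +
       (n - n1. + alpha - alpha1) / ((n1. + alpha1) * (1 + n + alpha)) +
       (n - n.1 + beta - beta1) / ((n.1 + beta1) * (1 + n + beta)))
  df0(ic = e_ic, ic025 = e_ic - 2 * sqrt(v_ic), ic_var = v_ic)
}

#' Bonferroni correction
#'
#' `P-adjusted = min(1, P-original * n)`; a result is declared significant
#' when the adjusted p-value is below 0.05, with `n` the number of
#' independent tests examined for the drug.
#'
#' @param p raw p-values.
#' @param n_tests the size of the test family (default `length(p)`).
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p, n_tests = length(p)) {
  stopifnot(n_tests >= 1)
  pmin(1, p * n_tests)
}

#' Positivity thresholds for the four algorithms
#'
#' The standard published criteria of FAERS disproportionality studies, all
#' strict inequalities: ROR positive when `a >= min_a` and the 95% CI lower
#' bound exceeds 1; PRR positive when `PRR >= 2`, `chi2 >= 4` and
#' `a >= min_a`; BCPNN positive when `IC025 > 0`; MGPS positive when
#' `EBGM05 > 2`. A term is a signal only when all four agree.
#'
#' @param ror_ci_lower,prr_min,prr_chi2_min,ic025_min,ebgm05_min,min_a
#'   numeric cut-offs.
#' @return a list of class `pv_thresholds`.
#' @export
pv_thresholds <- function(ror_ci_lower = 1, prr_min = 2, prr_chi2_min = 4,
                          ic025_min = 0, ebgm05_min = 2, min_a = 3) {
  structure(list(ror_ci_lower = ror_ci_lower, prr_min = prr_min,
                 prr_chi2_min = prr_chi2_min, ic025_min = ic025_min,
                 ebgm05_min = ebgm05_min, min_a = min_a),
            class = "pv_thresholds")
}

#' All four disproportionality statistics for a set of tables
#'
#' Computes ROR, PRR + chi-squared, the BCPNN information component and the
#' gamma-Poisson-shrinker EBGM for every contingency table of one drug and
#' level, applies Bonferroni correction over the evaluable terms, and flags
#' four-way positivity.
#'
#' @param ct a [build_contingency()] result.
#' @param prior a [fit_gps_prior()] result; fitted on `ct` when `NULL`.
#' @param thresholds a [pv_thresholds()] list.
#' @param yates use the Yates-corrected chi-squared (default FALSE).
#' @param n_tests Bonferroni family size; defaults to the number of
#'   evaluable terms in `ct`.
#' @return data.frame of class `signal_stats` with the table cells, all
#'   estimates and intervals, per-algorithm flags and the conjunction
#'   `positive`; the fitted prior is attached as attribute `prior`.
#' @export
signal_stats <- function(ct, prior = NULL, thresholds = pv_thresholds(),
                         yates = FALSE, n_tests = NULL) {
  stopifnot(nrow(ct) >= 1L)
  if (is.null(prior)) prior <- fit_gps_prior(ct)
  a <- ct$a; b <- ct$b; c <- ct$c; d <- ct$d
  r <- ror_stat(a, b, c, d)
  p <- prr_stat(a, b, c, d, yates = yates)
  bc <- bcpnn_stat(a, b, c, d)
  eb <- ebgm_stat(a, expected_count(ct), prior)
  if (is.null(n_tests)) n_tests <- sum(is.finite(p$p_raw))
  p_adj <- bonferroni_adjust(p$p_raw, max(n_tests, 1L))

  th <- thresholds
  flag_ror <- !is.na(r$ror_l) & a >= th$min_a & r$ror_l > th$ror_ci_lower
  flag_prr <- !is.na(p$prr) & p$prr >= th$prr_min &
    !is.na(p$chi2) & p$chi2 >= th$prr_chi2_min & a >= th$min_a
  flag_bcpnn <- bc$ic025 > th$ic025_min
  flag_mgps <- eb$ebgm05 > th$ebgm05_min
  out <- df0(drug = ct$drug, level = ct$level, term = ct$term,
             a = a, b = b, c = c, d = d,
             ror = r$ror, ror_l = r$ror_l, ror_u = r$ror_u,
             prr = p$prr, chi2 = p$chi2, p_raw = p$p_raw, p_adj = p_adj,
             ic = bc$ic, ic025 = bc$ic025,
             ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
             flag_ror = flag_ror, flag_prr = flag_prr,
             flag_bcpnn = flag_bcpnn, flag_mgps = flag_mgps,
             positive = flag_ror & flag_prr & flag_bcpnn & flag_mgps)
  attr(out, "prior") <- prior
  attr(out, "n_tests") <- n_tests
  class(out) <- c("signal_stats", "data.frame")
  out
}

#' Chi-squared test on SOC composition ratios
#'
#' Pearson chi-squared (no continuity correction) on the r x 2 table of
#' per-SOC report counts for two drugs, testing whether the two composition
#' ratios differ; df = r - 1.
#'
#' @param counts_a,counts_b per-SOC counts for the two drugs, aligned.
#' @return list with `chi2`, `df`, `p`.
#' @export
composition_chi2 <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 2L)
  m <- cbind(counts_a, counts_b)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal in the composition table")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Volcano-plot table
#'
#' One row per term: `log2(ROR)` on the x axis and `-log10(P-adjusted)` on
#' the y axis (an adjusted p of 1 maps to 0). Terms with undefined or
#' non-positive ROR are skipped with a warning.
#'
#' @param stats a [signal_stats()] result.
#' @return data.frame with columns `term`, `log2_ror`, `neg_log10_p_adj`,
#'   `positive`.
#' @export
volcano_table <- function(stats) {
  ok <- !is.na(stats$ror) & stats$ror > 0
  if (any(!ok))
    warning(sprintf("%d term(s) with undefined or non-positive ROR skipped",
                    sum(!ok)))
  s <- stats[ok, , drop = FALSE]
  df0(term = s$term, log2_ror = log2(s$ror),
      neg_log10_p_adj = -log10(s$p_adj), positive = s$positive)
}
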