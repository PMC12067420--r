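# Multi-item gamma Poisson shrinker (empirical Bayes).
#
# Model: the true reporting ratio lambda of a drug-event pair follows a
# two-component gamma mixture prior
#   lambda ~ p * Gamma(alpha1, beta1) + (1 - p) * Gamma(alpha2, beta2)
# (shape/rate). Given the baseline expectation E = (a+b)(a+c)/n, the
# observed count a is Poisson(lambda * E), so marginally a follows a
# mixture of negative binomials; the prior is fitted by maximizing that
# marginal likelihood over all tables, and each table's posterior is again
# a two-component gamma mixture.

gps_marginal_loglik <- function(a, E, alpha1, beta1, alpha2, beta2, p_mix) {
  l1 <- stats::dnbinom(a, size = alpha1, prob = beta1 / (beta1 + E),
                       log = TRUE)
  l2 <- stats::dnbinom(a, size = alpha2, prob = beta2 / (beta2 + E),
                       log = TRUE)
  m <- pmax(l1, l2)
  m + log(p_mix * exp(l1 - m) + (1 - p_mix) * exp(l2 - m))
}

#' Fit the gamma-mixture prior of the gamma Poisson shrinker
#'
#' Maximizes the marginal likelihood of the observed counts under the
#' two-component negative-binomial mixture induced by the gamma mixture
#' prior, using log-parameterized bounded quasi-Newton (L-BFGS-B) from five
#' fixed starting points, including the conventional start
#' `(0.2, 0.1, 2, 4, 1/3)`.
#'
#' @param ct a [build_contingency()] result, or a data.frame with columns
#'   `a` and `E` (observed counts and independence expectations).
#' @return an object of class `gps_prior`: `alpha1`, `beta1`, `alpha2`,
#'   `beta2`, `p_mix`, the attained `loglik`, and `n_tables`.
#' @export
fit_gps_prior <- function(ct) {
  E <- if (!is.null(ct$E)) ct$E else expected_count(ct)
  a <- ct$a
  keep <- is.finite(E) & E > 0
  a <- a[keep]; E <- E[keep]
  if (length(a) < 2L)
    stop("at least 2 tables with positive expected counts are required")
  if (length(a) < 10L)
    warning("fewer than 10 tables: the empirical-Bayes prior may be unstable")

  negll <- function(th) {
    alpha1 <- exp(th[1]); beta1 <- exp(th[2])
    alpha2 <- exp(th[3]); beta2 <- exp(th[4])
    p <- stats::plogis(th[5])
    -sum(gps_marginal_loglik(a, E, alpha1, beta1, alpha2, beta2, p))
  }
  starts <- list(c(0.2, 0.1, 2, 4, 1 / 3),
                 c(1, 1, 1, 1, 0.5),
                 c(0.5, 0.5, 5, 5, 0.2),
                 c(2, 2, 0.2, 0.2, 0.5),
                 c(0.1, 0.1, 10, 10, 0.1))
  best <- NULL
  for (s in starts) {
    th0 <- c(log(s[1:4]), stats::qlogis(s[5]))
    fit <- tryCatch(
      stats::optim(th0, negll, method = "L-BFGS-B",
                   lower = c(rep(-12, 4), -10), upper = c(rep(12, 4), 10),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("gamma-Poisson prior fit failed to converge from all starts")
  th <- best$par
  structure(list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                 alpha2 = exp(th[3]), beta2 = exp(th[4]),
                 p_mix = stats::plogis(th[5]),
                 loglik = -best$value, n_tables = length(a),
                 convergence = best$convergence),
            class = "gps_prior")
}

#' @export
print.gps_prior <- function(x, ...) {
  cat(sprintf(paste0("<gps_prior> p = %.3f * Gamma(%.3g, %.3g) + ",
                     "%.3f * Gamma(%.3g, %.3g)\n"),
              x$p_mix, x$alpha1, x$beta1, 1 - x$p_mix, x$alpha2, x$beta2))
  cat(sprintf("  prior mean %.3f; fitted on %d tables (loglik %.2f)\n",
              gps_prior_mean(x), x$n_tables, x$loglik))
  invisible(x)
}

#' Mean of the fitted gamma-mixture prior
#'
#' @param prior a `gps_prior`.
#' @return `p * alpha1/beta1 + (1 - p) * alpha2/beta2`.
#' @export
gps_prior_mean <- function(prior) {
  prior$p_mix * prior$alpha1 / prior$beta1 +
    (1 - prior$p_mix) * prior$alpha2 / prior$beta2
}

#' Empirical Bayes geometric mean and its lower 5th percentile
#'
#' The posterior of lambda given count `a` and expectation `E` is the
#' gamma mixture with components `Gamma(alpha_i + a, beta_i + E)` and
#' posterior weight from the component marginal likelihoods.
#' `EBGM = 2^(E[log2 lambda | a])` and `EBGM05` is the 5th percentile of
#' the posterior, found by bisection on the mixture CDF to 1e-8.
#'
#' @param a observed counts (vectorized).
#' @param E independence expectations.
#' @param prior a [fit_gps_prior()] result.
#' @return data.frame with columns `ebgm`, `ebgm05`.
#' @export
ebgm_stat <- function(a, E, prior) {
  stopifnot(inherits(prior, "gps_prior"))
  if (any(!is.finite(E) | E <= 0)) stop("all expected counts must be > 0")
  l1 <- log(prior$p_mix) +
    stats::dnbinom(a, size = prior$alpha1,
                   prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- log(1 - prior$p_mix) +
    stats::dnbinom(a, size = prior$alpha2,
                   prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  q <- 1 / (1 + exp(l2 - l1))  # posterior weight of component 1

  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  e_log <- q * (digamma(s1) - log(r1)) + (1 - q) * (digamma(s2) - log(r2))
  ebgm <- exp(e_log)

  ebgm05 <- gps_mixture_quantile(0.05, q, s1, r1, s2, r2)
  df0(ebgm = ebgm, ebgm05 = ebgm05)
}

# Vectorized bisection for a quantile of the two-component gamma mixture.
gps_mixture_quantile <- function(prob, q, s1, r1, s2, r2, tol = 1e-8) {
  lo <- rep(0, length(s1))
  hi <- pmax(stats::qgamma(0.99999, s1, r1),
             stats::qgamma(0.99999, s2, r2)) + 1
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    f <- q * stats::pgamma(mid, s1, r1) + (1 - q) * stats::pgamma(mid, s2, r2)
    below <- f < prob
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}
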