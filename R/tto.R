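# Time-to-onset (TTO): interval in days from therapy start (START_DT) to
# event onset (EVENT_DT), with strict exclusion of missing, partial and
# negative intervals; summaries, Weibull fitting, failure-type
# classification, and between-group rank tests.

TTO_BREAKS <- c(-0.5, 30, 60, 90, 120, 180, 360, 720, Inf)
TTO_LABELS <- c("0-30", "31-60", "61-90", "91-120", "121-180", "181-360",
                "361-720", ">720")

#' Extract time-to-onset samples from a case set
#'
#' `days = EVENT_DT - START_DT` in calendar days. Cases with a missing
#' date, a partial date (YYYYMM or shorter, or otherwise unparseable), or a
#' negative interval (event before therapy start) are excluded and tallied;
#' day-0 events are kept. With `by = "pt"` or `"soc"` a case contributes
#' its interval to every term it reports.
#'
#' @param caseset a `case_set`; for `by != "overall"` it must have events
#'   attached ([attach_events()]).
#' @param by `"overall"`, `"pt"` or `"soc"`.
#' @param signal_only with `by != "overall"`, restrict to terms passing the
#'   minimum-count filter (default TRUE).
#' @return a data.frame of class `tto_samples` with columns `label`,
#'   `caseid`, `days`, and attribute `exclusions`: per-label tallies
#'   `n_input`, `n_used`, `n_missing`, `n_partial`, `n_negative`.
#' @export
compute_tto <- function(caseset, by = c("overall", "pt", "soc"),
                        signal_only = TRUE) {
  by <- match.arg(by)
  stopifnot(inherits(caseset, "case_set"))
  cs <- caseset$cases
  ev_ok <- is_dt8(cs$event_dt)
  st_ok <- is_dt8(cs$start_dt)
  missing <- !nzchar(cs$event_dt) | !nzchar(cs$start_dt)
  partial <- !missing & (!ev_ok | !st_ok)
  days <- rep(NA_integer_, nrow(cs))
  both <- ev_ok & st_ok
  days[both] <- as.integer(parse_dt8(cs$event_dt[both]) -
                             parse_dt8(cs$start_dt[both]))
  negative <- both & days < 0
  used <- both & !negative
  status <- ifelse(missing, "missing",
                   ifelse(partial, "partial",
                          ifelse(negative, "negative", "used")))

  if (by == "overall") {
    lab <- rep("overall", nrow(cs))
    out <- df0(label = lab[used], caseid = cs$caseid[used],
               days = days[used])
    excl <- tto_tally("overall", status)
  } else {
    if (is.null(caseset$events))
      stop("attach_events() must be run before per-term TTO")
    ev <- caseset$events
    if (signal_only) ev <- ev[ev$in_signal, , drop = FALSE]
    i <- match(ev$caseid, cs$caseid)
    lab <- if (by == "pt") ev$pt else ev$soc
    st <- status[i]
    out <- df0(label = lab[st == "used"], caseid = ev$caseid[st == "used"],
               days = days[i][st == "used"])
    excl <- do.call(rbind, lapply(sort(unique(lab)), function(l)
      tto_tally(l, st[lab == l])))
  }
  rownames(out) <- NULL
  structure(out, exclusions = excl,
            class = c("tto_samples", "data.frame"))
}

tto_tally <- function(label, status) {
  df0(label = label, n_input = length(status),
      n_used = sum(status == "used"), n_missing = sum(status == "missing"),
      n_partial = sum(status == "partial"),
      n_negative = sum(status == "negative"))
}

#' Summary of one time-to-onset sample
#'
#' Median and quartiles (linear interpolation, quantile type 7) plus counts
#' and percentages over eight onset-period bins
#' (0-30, 31-60, 61-90, 91-120, 121-180, 181-360, 361-720, >720 days;
#' day-0 events fall in the first bin).
#'
#' @param days non-negative integer vector of onset intervals.
#' @return list with `n`, `median`, `q1`, `q3`, and `histogram`
#'   (data.frame `bin`, `count`, `percent`).
#' @export
tto_summary <- function(days) {
  if (inherits(days, "tto_samples")) days <- days$days
  if (!length(days)) stop("empty time-to-onset sample")
  qs <- stats::quantile(days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  cnt <- table(cut(days, breaks = TTO_BREAKS, labels = TTO_LABELS))
  list(n = length(days), median = qs[2], q1 = qs[1], q3 = qs[3],
       histogram = df0(bin = TTO_LABELS, count = as.integer(cnt),
                       percent = case_proportion(as.integer(cnt),
                                                 length(days),
                                                 digits = 2)))
}

#' Maximum-likelihood Weibull fit of onset intervals
#'
#' Fits scale (alpha, days) and shape (beta) by maximum likelihood on the
#' positive day values (day-0 events are moved to 0.5 days, inside the
#' support), with 95% confidence intervals from the observed-information
#' normal approximation on the log parameters, and classifies the hazard as
#' early / random / wear-out failure type from the shape interval.
#'
#' @param days onset intervals (n >= 10, at least 2 distinct values).
#' @param zero_days value substituted for day-0 events (default 0.5).
#' @return an object of class `weibull_fit`: `scale`, `scale_ci`, `shape`,
#'   `shape_ci`, `n`, `loglik`, `failure_type`.
#' @export
fit_weibull <- function(days, zero_days = 0.5) {
  if (inherits(days, "tto_samples")) days <- days$days
  stopifnot(all(days >= 0))
  if (length(days) < 10L)
    stop("at least 10 onset intervals are required")
  t <- ifelse(days <= 0, zero_days, as.numeric(days))
  if (length(unique(t)) < 2L)
    stop("degenerate sample: all onset intervals equal")

  negll <- function(th) {
    v <- suppressWarnings(
      -sum(stats::dweibull(t, shape = exp(th[1]), scale = exp(th[2]),
                           log = TRUE)))
    if (!is.finite(v)) 1e10 else v
  }
  # method-of-moments-on-logs start
  sh0 <- min(max(1.2 / stats::sd(log(t)), 0.05), 20)
  sc0 <- exp(mean(log(t)) + 0.5772 / sh0)
  fit <- stats::optim(c(log(sh0), log(sc0)), negll, method = "BFGS",
                      hessian = TRUE)
  vc <- tryCatch(solve(fit$hessian), error = function(e)
    matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  shape <- exp(fit$par[1]); scale <- exp(fit$par[2])
  shape_ci <- exp(fit$par[1] + c(-1, 1) * 1.96 * se[1])
  scale_ci <- exp(fit$par[2] + c(-1, 1) * 1.96 * se[2])
  structure(list(scale = scale, scale_ci = scale_ci,
                 shape = shape, shape_ci = shape_ci,
                 n = length(t), loglik = -fit$value,
                 failure_type = classify_failure(shape, shape_ci[1],
                                                 shape_ci[2])),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(paste0("<weibull_fit> n = %d: scale %.1f (%.1f-%.1f) days, ",
                     "shape %.3f (%.3f-%.3f), %s failure type\n"),
              x$n, x$scale, x$scale_ci[1], x$scale_ci[2],
              x$shape, x$shape_ci[1], x$shape_ci[2],
              gsub("_", "-", x$failure_type)))
  invisible(x)
}

#' Failure-type classification from the Weibull shape parameter
#'
#' Early failure (risk decreasing over time) when the shape is below 1 and
#' its 95% CI stays below 1; wear-out failure (risk increasing) when the
#' shape exceeds 1 and its CI stays above 1; random failure (stable risk)
#' when the CI contains 1.
#'
#' @param shape estimated Weibull shape, or a `weibull_fit`.
#' @param lower,upper 95% confidence bounds of the shape.
#' @return one of `"early"`, `"random"`, `"wear_out"`.
#' @export
classify_failure <- function(shape, lower, upper) {
  if (inherits(shape, "weibull_fit")) {
    lower <- shape$shape_ci[1]; upper <- shape$shape_ci[2]
    shape <- shape$shape
  }
  if (shape < 1 && upper < 1) "early"
  else if (shape > 1 && lower > 1) "wear_out"
  else "random"
}

#' Kruskal-Wallis test across time-to-onset groups
#'
#' Rank-based H statistic with tie correction and a chi-squared reference
#' with k - 1 df. A fully tied pooled sample (tie correction 0/0) is
#' reported as H = 0, p = 1.
#'
#' @param groups list of two or more numeric vectors (each non-empty), or a
#'   `tto_samples` frame split by `label`.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (inherits(groups, "tto_samples"))
    groups <- split(groups$days, groups$label)
  if (length(groups) < 2L) stop("at least two groups are required")
  stopifnot(all(lengths(groups) >= 1L))
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("at least 3 observations in total are required")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  res <- stats::kruskal.test(x, g)
  list(H = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}
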