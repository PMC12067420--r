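# Synthetic spontaneous-report generator.
#
# Emits FAERS-shaped DEMO/DRUG/REAC/OUTC/THER/INDI tables with known ground
# truth (planted drug-event relative risks, duplicate case versions, deleted
# cases, Weibull onset intervals) so the whole pipeline can be validated
# without access to the real quarterly dumps.

#' Configuration for the synthetic report generator
#'
#' Defines the reporting regime the generator emulates: a population of
#' reports, each with one primary-suspect (index) drug, one or more reported
#' preferred terms (PTs), optional concomitant drugs, demographics, and a
#' Weibull-distributed therapy-start to event-onset interval. Drug-event
#' co-reporting is multinomial with probability proportional to
#' `event_weights * rr(drug, event)`, so planted pairs are over-reported by
#' their relative risk.
#'
#' @param n_drugs,n_events,n_reports population dimensions.
#' @param drug_weights,event_weights background sampling weights (probability
#'   simplexes; default uniform).
#' @param planted_pairs `NULL` or a data.frame with columns `drug`, `event`
#'   (integer ids) and `rr` (relative risk, >= 0). All other pairs have
#'   relative risk 1.
#' @param events_per_report_mean events per report are `1 + Poisson(mean)`,
#'   mirroring multi-PT reports.
#' @param duplicate_rate fraction of cases that gain 1-2 extra report
#'   versions (same CASEID, new PRIMARYID, equal-or-later FDA_DT).
#' @param deleted_rate fraction of CASEIDs appended to the deleted-case list.
#' @param missing_event_date_rate fraction of reports whose EVENT_DT is
#'   emitted blank or truncated to YYYYMM, to exercise onset exclusions.
#' @param concomitant_prob probability that a case carries at least one
#'   concomitant (role C) drug.
#' @param onset_scale,onset_shape per-drug Weibull onset parameters in days
#'   (recycled across drugs).
#' @param n_socs number of system organ classes the PTs are mapped onto.
#' @param demographic_mix named list of categorical probabilities (see
#'   defaults in the source); any element may be overridden.
#' @param date_window therapy start dates are uniform over this
#'   `c(from, to)` window (8-digit text).
#' @param seed integer seed; identical configurations generate byte-identical
#'   tables.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 8, n_events = 50, n_reports = 5000,
                         drug_weights = NULL, event_weights = NULL,
                         planted_pairs = NULL,
                         events_per_report_mean = 2,
                         duplicate_rate = 0.1, deleted_rate = 0.05,
                         missing_event_date_rate = 0.2,
                         concomitant_prob = 0.3,
                         onset_scale = 100, onset_shape = 0.7,
                         n_socs = 5,
                         demographic_mix = list(),
                         date_window = c("20150101", "20231231"),
                         seed = 1L) {
  mix <- list(
    sex = c(F = 0.36, M = 0.55, U = 0.09),
    age_mean = 70, age_sd = 12, age_missing = 0.35, age_mon = 0.02,
    wt_missing = 0.85, wt_mean = 75, wt_sd = 15,
    countries = c(US = 0.60, UK = 0.10, CA = 0.05, DE = 0.08, FR = 0.05,
                  JP = 0.12),
    reporters = c(CN = 0.55, HP = 0.07, LW = 0.002, MD = 0.22, OT = 0.04,
                  PH = 0.05, U = 0.068),
    outcomes = c(DE = 0.15, HO = 0.18, LT = 0.01, DS = 0.005, CA = 0.001,
                 RI = 0.001, OT = 0.12, none = 0.533),
    indications = c(INDICATION_1 = 0.6, INDICATION_2 = 0.2,
                    INDICATION_3 = 0.1, INDICATION_4 = 0.06,
                    INDICATION_5 = 0.04)
  )
  mix[names(demographic_mix)] <- demographic_mix

  cfg <- list(
    n_drugs = as.integer(n_drugs), n_events = as.integer(n_events),
    n_reports = as.integer(n_reports),
    drug_weights = drug_weights %||% rep(1 / n_drugs, n_drugs),
    event_weights = event_weights %||% rep(1 / n_events, n_events),
    planted_pairs = planted_pairs,
    events_per_report_mean = events_per_report_mean,
    duplicate_rate = duplicate_rate, deleted_rate = deleted_rate,
    missing_event_date_rate = missing_event_date_rate,
    concomitant_prob = concomitant_prob,
    onset_scale = rep_len(onset_scale, n_drugs),
    onset_shape = rep_len(onset_shape, n_drugs),
    n_socs = as.integer(n_socs),
    demographic_mix = mix,
    date_window = date_window,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_reports >= 1L, cfg$n_drugs >= 1L, cfg$n_events >= 1L)
  for (w in c("drug_weights", "event_weights")) {
    wt <- cfg[[w]]
    if (any(wt < 0) || abs(sum(wt) - 1) > 1e-9)
      stop(w, " must be a probability simplex (non-negative, summing to 1)")
  }
  for (r in c("duplicate_rate", "deleted_rate", "missing_event_date_rate",
              "concomitant_prob")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must lie in [0, 1]")
  }
  stopifnot(all(cfg$onset_scale > 0), all(cfg$onset_shape > 0))
  pp <- cfg$planted_pairs
  if (!is.null(pp)) {
    stopifnot(all(c("drug", "event", "rr") %in% names(pp)))
    if (any(pp$drug < 1 | pp$drug > cfg$n_drugs) ||
        any(pp$event < 1 | pp$event > cfg$n_events))
      stop("planted_pairs reference drug/event ids outside the configuration")
    stopifnot(all(pp$rr >= 0))
  }
  if (!all(is_dt8(cfg$date_window))) stop("date_window must be 8-digit dates")
  invisible(cfg)
}

synth_drug_names <- function(n) sprintf("DRUG_%02d", seq_len(n))
synth_event_names <- function(n) sprintf("PT_%03d", seq_len(n))

#' Relative-risk matrix implied by a configuration
#'
#' @param config a [synth_config()].
#' @return an `n_drugs x n_events` matrix, 1 everywhere except planted pairs.
#' @export
true_rr_matrix <- function(config) {
  rr <- matrix(1, config$n_drugs, config$n_events,
               dimnames = list(synth_drug_names(config$n_drugs),
                               synth_event_names(config$n_events)))
  pp <- config$planted_pairs
  if (!is.null(pp)) rr[cbind(pp$drug, pp$event)] <- pp$rr
  rr
}

#' Generate a synthetic report population
#'
#' Draws `n_reports` single-version cases: one DEMO row per report, exactly
#' one primary-suspect DRUG row per case for its index drug (plus optional
#' concomitant rows), REAC rows with PT names (distinct within a case), one
#' THER row with the therapy START_DT, and EVENT_DT placed in DEMO at
#' `START_DT + Weibull(scale, shape)` days. Event identities are sampled with
#' probability proportional to `event_weights * rr(drug, event)`.
#'
#' @param config a [synth_config()].
#' @return a list with elements `tables` (class `raw_report_tables`) and
#'   `truth` (class `ground_truth`: `true_rr`, `canonical_caseids`,
#'   `deleted_caseids`, `survivors`, `true_onset_params`).
#' @export
generate_reports <- function(config) {
  validate_synth_config(config)
  with_seed(config$seed, generate_reports_impl(config))
}

generate_reports_impl <- function(cfg) {
  n <- cfg$n_reports
  mix <- cfg$demographic_mix
  drug_names <- synth_drug_names(cfg$n_drugs)
  event_names <- synth_event_names(cfg$n_events)
  rr <- true_rr_matrix(cfg)

  caseid <- as.character(10000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")  # version 1

  drug_idx <- sample.int(cfg$n_drugs, n, replace = TRUE,
                         prob = cfg$drug_weights)

  # Events: 1 + Poisson slots per report, iid categorical within the report's
  # index drug, then collapsed to distinct (report, PT).
  k <- 1L + stats::rpois(n, cfg$events_per_report_mean)
  rid <- rep.int(seq_len(n), k)
  ev <- integer(length(rid))
  for (d in seq_len(cfg$n_drugs)) {
    sel <- drug_idx[rid] == d
    if (!any(sel)) next
    ev[sel] <- sample.int(cfg$n_events, sum(sel), replace = TRUE,
                          prob = cfg$event_weights * rr[d, ])
  }
  pair <- !duplicated(cbind(rid, ev))
  reac <- df0(primaryid = primaryid[rid[pair]], pt = event_names[ev[pair]])

  # Dates: therapy start uniform in the window, onset from the index drug's
  # Weibull, FDA receipt shortly after the event.
  win <- as.Date(cfg$date_window, format = "%Y%m%d")
  start <- win[1] + sample.int(as.integer(win[2] - win[1]) + 1L, n,
                               replace = TRUE) - 1L
  onset <- round(stats::rweibull(n, shape = cfg$onset_shape[drug_idx],
                                 scale = cfg$onset_scale[drug_idx]))
  event <- start + onset
  fda <- event + sample.int(61L, n, replace = TRUE) - 1L

  event_dt <- fmt_dt8(event)
  miss <- stats::runif(n) < cfg$missing_event_date_rate
  trunc6 <- miss & stats::runif(n) < 0.5
  event_dt[miss] <- ""
  event_dt[trunc6] <- substr(fmt_dt8(event[trunc6]), 1, 6)

  # Demographics
  age_years <- round(stats::rnorm(n, mix$age_mean, mix$age_sd))
  age_years <- pmax(age_years, 1)
  age <- as.character(age_years)
  age_cod <- rep("YR", n)
  as_mon <- stats::runif(n) < mix$age_mon
  age[as_mon] <- as.character(age_years[as_mon] * 12L)
  age_cod[as_mon] <- "MON"
  age_na <- stats::runif(n) < mix$age_missing
  age[age_na] <- ""
  age_cod[age_na] <- ""

  sex <- sample(c("F", "M", ""), n, replace = TRUE, prob = mix$sex)
  wt <- as.character(round(stats::rnorm(n, mix$wt_mean, mix$wt_sd), 1))
  wt[stats::runif(n) < mix$wt_missing] <- ""
  country <- sample(names(mix$countries), n, replace = TRUE,
                    prob = mix$countries)
  occp <- sample(names(mix$reporters), n, replace = TRUE,
                 prob = mix$reporters)
  occp[occp == "U"] <- ""

  demo <- df0(primaryid = primaryid, caseid = caseid, fda_dt = fmt_dt8(fda),
              event_dt = event_dt, age = age, age_cod = age_cod, sex = sex,
              wt = wt, reporter_country = country, occp_cod = occp)

  # DRUG: the PS row, plus 0-2 concomitant rows drawn from the other drugs.
  p <- cfg$concomitant_prob
  n_con <- sample(0:2, n, replace = TRUE, prob = c(1 - p, 0.7 * p, 0.3 * p))
  con_rid <- rep.int(seq_len(n), n_con)
  con_drug <- character(length(con_rid))
  if (length(con_rid) && cfg$n_drugs > 1L) {
    shift <- sample.int(cfg$n_drugs - 1L, length(con_rid), replace = TRUE)
    con_drug <- drug_names[((drug_idx[con_rid] - 1L + shift) %% cfg$n_drugs) + 1L]
  }
  con_seq <- unlist(lapply(n_con[n_con > 0L], seq_len), use.names = FALSE) + 1L
  drug <- rbind(
    df0(primaryid = primaryid, drug_seq = "1", role_cod = "PS",
        drugname = drug_names[drug_idx]),
    if (length(con_rid))
      df0(primaryid = primaryid[con_rid], drug_seq = as.character(con_seq),
          role_cod = "C", drugname = con_drug)
  )
  drug <- drug[order(match(drug$primaryid, primaryid),
                     as.integer(drug$drug_seq)), , drop = FALSE]
  rownames(drug) <- NULL

  out_code <- sample(names(mix$outcomes), n, replace = TRUE,
                     prob = mix$outcomes)
  has_out <- out_code != "none"
  outc <- df0(primaryid = primaryid[has_out], outc_cod = out_code[has_out])

  ther <- df0(primaryid = primaryid, dsg_drug_seq = "1",
              start_dt = fmt_dt8(start), end_dt = "")
  indi <- df0(primaryid = primaryid, indi_drug_seq = "1",
              indi_pt = sample(names(mix$indications), n, replace = TRUE,
                               prob = mix$indications))

  tables <- raw_report_tables(demo = demo, drug = drug, reac = reac,
                              outc = outc, ther = ther, indi = indi,
                              deleted = character())
  survivors <- primaryid
  names(survivors) <- caseid
  truth <- structure(list(
    true_rr = rr,
    canonical_caseids = caseid,
    deleted_caseids = character(),
    survivors = survivors,
    true_onset_params = df0(drug = drug_names,
                            scale = cfg$onset_scale,
                            shape = cfg$onset_shape)
  ), class = "ground_truth")
  list(tables = tables, truth = truth)
}

#' Inject duplicate report versions and deleted cases
#'
#' A `duplicate_rate` fraction of cases gains one or two extra versions with
#' a fresh (larger) PRIMARYID and an equal-or-later FDA_DT; all child tables
#' are copied verbatim under the new PRIMARYID, so deduplication must operate
#' on DEMO keys alone. A `deleted_rate` fraction of CASEIDs is appended to
#' the deleted-case list. The ground truth records the intended survivor of
#' every case (latest FDA_DT, ties broken by the larger PRIMARYID).
#'
#' @param tables,truth output of [generate_reports()].
#' @param config the [synth_config()] used to generate them.
#' @return a list with updated `tables` and `truth`.
#' @export
inject_versions_and_deletions <- function(tables, truth, config) {
  with_seed(config$seed + 1L, {
    demo <- tables$demo
    caseids <- truth$canonical_caseids
    n_dup <- round(config$duplicate_rate * length(caseids))
    if (n_dup > 0L) {
      dup_cases <- sample(caseids, n_dup)
      extra <- sample(1:2, n_dup, replace = TRUE)
      base <- demo[match(dup_cases, demo$caseid), , drop = FALSE]
      idx <- rep.int(seq_len(n_dup), extra)
      ver <- unlist(lapply(extra, seq_len), use.names = FALSE) + 1L
      new_demo <- base[idx, , drop = FALSE]
      old_pid <- new_demo$primaryid
      new_demo$primaryid <- paste0(new_demo$caseid, ver)
      new_demo$fda_dt <- fmt_dt8(parse_dt8(new_demo$fda_dt) +
                                   sample(0:90, length(idx), replace = TRUE))
      tables$demo <- rbind(demo, new_demo)
      for (tb in c("drug", "reac", "outc", "ther", "indi")) {
        child <- tables[[tb]]
        copies <- lapply(seq_along(old_pid), function(i) {
          rows <- child[child$primaryid == old_pid[i], , drop = FALSE]
          rows$primaryid <- rep(new_demo$primaryid[i], nrow(rows))
          rows
        })
        tables[[tb]] <- rbind(child, do.call(rbind, copies))
        rownames(tables[[tb]]) <- NULL
      }
      rownames(tables$demo) <- NULL
      # recompute intended survivors: max (fda_dt, primaryid) per case
      d <- tables$demo
      o <- order(d$caseid, d$fda_dt, as.numeric(d$primaryid))
      d <- d[o, , drop = FALSE]
      last <- !duplicated(d$caseid, fromLast = TRUE)
      survivors <- d$primaryid[last]
      names(survivors) <- d$caseid[last]
      truth$survivors <- survivors[truth$canonical_caseids]
    }
    n_del <- round(config$deleted_rate * length(caseids))
    if (n_del > 0L) {
      deleted <- sort(sample(caseids, n_del))
      tables$deleted <- deleted
      truth$deleted_caseids <- deleted
    }
    list(tables = tables, truth = truth)
  })
}

#' Preferred-term to system-organ-class map for synthetic data
#'
#' Assigns the configuration's PTs round-robin to `n_socs` synthetic SOCs.
#'
#' @param config a [synth_config()].
#' @return data.frame with columns `pt`, `soc`.
#' @export
synth_term_map <- function(config) {
  pts <- synth_event_names(config$n_events)
  df0(pt = pts,
      soc = sprintf("SOC_%d", ((seq_along(pts) - 1L) %% config$n_socs) + 1L))
}
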