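# Case-level ingestion: deduplication, deleted-case handling, target-drug
# selection, and event attachment with the minimum-count filter.

#' Deduplicate report versions
#'
#' Spontaneous-report cases accumulate versions over quarters under one
#' CASEID. For each CASEID the most recent FDA_DT wins; if CASEID and FDA_DT
#' are equal, the higher PRIMARYID (the more recently submitted report) is
#' kept. Rows whose FDA_DT is not a parseable 8-digit date are excluded with
#' a warning count.
#'
#' @param demo the DEMO table of a [raw_report_tables()] object.
#' @return character vector of surviving PRIMARYIDs, one per CASEID, with
#'   attribute `n_excluded` (rows dropped for unparseable FDA_DT).
#' @export
deduplicate <- function(demo) {
  ok <- is_dt8(demo$fda_dt)
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    warning(sprintf("%d DEMO row(s) excluded: unparseable FDA_DT", n_bad))
  d <- demo[ok, c("caseid", "fda_dt", "primaryid"), drop = FALSE]
  pid_num <- suppressWarnings(as.numeric(d$primaryid))
  pid_ord <- if (anyNA(pid_num)) xtfrm(d$primaryid) else pid_num
  o <- order(d$caseid, d$fda_dt, pid_ord)
  d <- d[o, , drop = FALSE]
  keep <- !duplicated(d$caseid, fromLast = TRUE)
  structure(d$primaryid[keep], n_excluded = n_bad)
}

#' Remove cases on the deleted-report list
#'
#' Quarterly packages ship a list of deleted CASEIDs; any surviving report
#' whose CASEID appears on it is excluded. Listed CASEIDs absent from the
#' survivors are a logged no-op.
#'
#' @param survivors PRIMARYIDs from [deduplicate()].
#' @param demo the DEMO table (to resolve PRIMARYID to CASEID).
#' @param deleted character vector of deleted CASEIDs.
#' @return filtered character vector of PRIMARYIDs.
#' @export
apply_deletions <- function(survivors, demo, deleted) {
  if (!length(deleted)) return(survivors)
  caseid <- demo$caseid[match(survivors, demo$primaryid)]
  unused <- setdiff(deleted, caseid)
  if (length(unused))
    message(sprintf("%d deleted CASEID(s) not present among survivors",
                    length(unused)))
  survivors[!(caseid %in% deleted)]
}

#' Define a target drug by synonym list and role filter
#'
#' Spontaneous-report databases have no harmonized drug coding, so a target
#' drug is identified by an explicit set of verbatim names. Matching is
#' exact on the normalized (case-folded, whitespace-trimmed) name; by
#' default only primary-suspect (PS) rows qualify.
#'
#' @param name canonical drug label used in outputs.
#' @param synonyms character vector of verbatim names to match.
#' @param roles role codes that qualify a case (subset of PS, SS, C, I).
#' @return an object of class `drug_query`.
#' @export
drug_query <- function(name, synonyms = name, roles = "PS") {
  synonyms <- synonyms[nzchar(trimws(synonyms))]
  if (!length(synonyms)) stop("synonym set must be non-empty")
  if (!all(roles %in% ROLE_CODES))
    stop("roles must be a subset of: ", paste(ROLE_CODES, collapse = ", "))
  structure(list(canonical_name = name,
                 synonyms = unique(norm_drugname(synonyms)),
                 role_filter = roles),
            class = "drug_query")
}

#' @rdname drug_query
#' @details `pirfenidone_query()` and `nintedanib_query()` return the
#'   verbatim name sets under which the two approved antifibrotics appear in
#'   FAERS and JADER, including trade names and the Japanese generic names.
#' @export
pirfenidone_query <- function() {
  drug_query("pirfenidone",
             c("PIRFENIDONE", "PIRESPA PIFENIDONE", "BLINDED PIRFENIDONE",
               "ESBRIET", "ピルフェニドン"))
}

#' @rdname drug_query
#' @export
nintedanib_query <- function() {
  drug_query("nintedanib",
             c("NINTEDANIB", "OFEV", "VARGATEF", "BIBF 1120",
               "ニンテダニブエタンスルホン酸塩"))
}

#' Select the cases of a target drug
#'
#' Retains deduplicated, non-deleted cases having at least one DRUG row
#' whose normalized name is in the query's synonym set and whose role code
#' is in the query's role filter (default: primary suspect only). Records
#' for each case the number of distinct concomitant drug names, the earliest
#' therapy start date of the matched drug rows, the single most serious
#' outcome code (DE > LT > HO > DS > CA > RI > OT), and the indication.
#'
#' @param tables a [raw_report_tables()] object.
#' @param query a [drug_query()].
#' @param survivors PRIMARYIDs to consider; defaults to
#'   `apply_deletions(deduplicate(tables$demo), tables$demo, tables$deleted)`.
#' @return an object of class `case_set`: a list with `cases` (one row per
#'   CASEID), `events` (populated by [attach_events()]) and the query.
#' @export
select_drug_cases <- function(tables, query, survivors = NULL) {
  stopifnot(inherits(tables, "raw_report_tables"),
            inherits(query, "drug_query"))
  if (is.null(survivors))
    survivors <- apply_deletions(deduplicate(tables$demo), tables$demo,
                                 tables$deleted)
  demo <- tables$demo[tables$demo$primaryid %in% survivors, , drop = FALSE]
  drug <- tables$drug[tables$drug$primaryid %in% survivors, , drop = FALSE]
  nm <- norm_drugname(drug$drugname)
  hit <- nm %in% query$synonyms & drug$role_cod %in% query$role_filter
  hits <- drug[hit, , drop = FALSE]
  pids <- unique(hits$primaryid)
  demo <- demo[match(pids, demo$primaryid), , drop = FALSE]

  # distinct non-target drug names per retained case (any role)
  on_case <- drug[drug$primaryid %in% pids, , drop = FALSE]
  other <- unique(df0(primaryid = on_case$primaryid,
                      nm = norm_drugname(on_case$drugname)))
  other <- other[!(other$nm %in% query$synonyms), , drop = FALSE]
  con_tab <- table(other$primaryid)
  con_count <- as.integer(con_tab[match(pids, names(con_tab))])
  con_count[is.na(con_count)] <- 0L

  # earliest therapy start among THER rows linked to the matched drug rows
  ther <- tables$ther
  cand <- ther[paste(ther$primaryid, ther$dsg_drug_seq) %in%
                 paste(hits$primaryid, hits$drug_seq), , drop = FALSE]
  start_dt <- rep("", length(pids))
  if (nrow(cand)) {
    dts <- parse_dt8(cand$start_dt)
    o <- order(cand$primaryid, is.na(dts), dts)
    cand <- cand[o, , drop = FALSE]
    first <- cand[!duplicated(cand$primaryid), , drop = FALSE]
    mi <- match(pids, first$primaryid)
    start_dt <- ifelse(is.na(mi), "", first$start_dt[mi])
  }

  # single most serious outcome per case
  outc <- tables$outc[tables$outc$primaryid %in% pids, , drop = FALSE]
  outcome <- rep("Missing", length(pids))
  if (nrow(outc)) {
    sev <- match(outc$outc_cod, OUTCOME_SEVERITY)
    o <- order(outc$primaryid, sev)
    outc <- outc[o, , drop = FALSE]
    first <- outc[!duplicated(outc$primaryid), , drop = FALSE]
    mi <- match(pids, first$primaryid)
    outcome[!is.na(mi)] <- first$outc_cod[mi[!is.na(mi)]]
  }

  indi <- tables$indi
  icand <- indi[paste(indi$primaryid, indi$indi_drug_seq) %in%
                  paste(hits$primaryid, hits$drug_seq), , drop = FALSE]
  mi <- match(pids, icand$primaryid)
  indication <- ifelse(is.na(mi), "", icand$indi_pt[mi])

  cases <- df0(caseid = demo$caseid, primaryid = pids,
               age = demo$age, age_cod = demo$age_cod, sex = demo$sex,
               wt = demo$wt, reporter_country = demo$reporter_country,
               occp_cod = demo$occp_cod, event_dt = demo$event_dt,
               start_dt = start_dt, outcome = outcome,
               indication = indication,
               concomitant_drug_count = con_count)
  structure(list(cases = cases, events = NULL, min_count = NA_integer_,
                 query = query),
            class = "case_set")
}

#' Attach adverse-event terms to a case set
#'
#' Each case gains its list of distinct preferred terms with system-organ-
#' class labels. Terms occurring fewer than `min_count` times across the
#' case set (counting distinct case-term pairs) are flagged out of signal
#' analysis but kept in the raw listing; terms missing from the map are
#' bucketed as `"UNMAPPED"` with a warning.
#'
#' @param caseset a [select_drug_cases()] result.
#' @param reac the REAC table of the same dataset.
#' @param term_map data.frame with columns `pt`, `soc`.
#' @param min_count minimum occurrences for a PT to enter signal analysis
#'   (default 3).
#' @return the `case_set` with an `events` data.frame
#'   (`caseid`, `pt`, `soc`, `count`, `in_signal`).
#' @export
attach_events <- function(caseset, reac, term_map, min_count = 3L) {
  stopifnot(inherits(caseset, "case_set"))
  cases <- caseset$cases
  sub <- reac[reac$primaryid %in% cases$primaryid, , drop = FALSE]
  ev <- unique(df0(caseid = cases$caseid[match(sub$primaryid,
                                               cases$primaryid)],
                   pt = sub$pt))
  soc <- term_map$soc[match(ev$pt, term_map$pt)]
  n_unmapped <- sum(is.na(soc))
  if (n_unmapped > 0L)
    warning(sprintf("%d PT(s) absent from the term map bucketed as UNMAPPED",
                    length(unique(ev$pt[is.na(soc)]))))
  soc[is.na(soc)] <- "UNMAPPED"
  cnt <- table(ev$pt)
  ev$soc <- soc
  ev$count <- as.integer(cnt[ev$pt])
  ev$in_signal <- ev$count >= min_count
  caseset$events <- ev
  caseset$min_count <- as.integer(min_count)
  caseset
}

#' Restrict a case set to monotherapy reports
#'
#' Sensitivity filter: keeps only cases reporting no concomitant drug
#' (distinct non-target drug name count of zero).
#'
#' @param caseset a `case_set` with `concomitant_drug_count` populated.
#' @return the filtered `case_set`.
#' @export
exclude_concomitant <- function(caseset) {
  stopifnot(inherits(caseset, "case_set"))
  keep <- caseset$cases$concomitant_drug_count == 0L
  caseset$cases <- caseset$cases[keep, , drop = FALSE]
  rownames(caseset$cases) <- NULL
  if (!is.null(caseset$events)) {
    caseset$events <- caseset$events[caseset$events$caseid %in%
                                       caseset$cases$caseid, , drop = FALSE]
    rownames(caseset$events) <- NULL
  }
  caseset
}

#' Distinct case-term pairs across all retained cases
#'
#' The background population for contingency tables: one row per distinct
#' (CASEID, PT) pair over every deduplicated, non-deleted case in the
#' dataset, with the SOC label attached.
#'
#' @param tables a [raw_report_tables()] object.
#' @param term_map data.frame with columns `pt`, `soc`.
#' @param survivors PRIMARYIDs to consider; defaults to dedup + deletions.
#' @return data.frame with columns `caseid`, `pt`, `soc`.
#' @export
all_case_events <- function(tables, term_map, survivors = NULL) {
  if (is.null(survivors))
    survivors <- apply_deletions(deduplicate(tables$demo), tables$demo,
                                 tables$deleted)
  demo <- tables$demo
  sub <- tables$reac[tables$reac$primaryid %in% survivors, , drop = FALSE]
  ev <- unique(df0(caseid = demo$caseid[match(sub$primaryid,
                                              demo$primaryid)],
                   pt = sub$pt))
  soc <- term_map$soc[match(ev$pt, term_map$pt)]
  soc[is.na(soc)] <- "UNMAPPED"
  ev$soc <- soc
  rownames(ev) <- NULL
  ev
}

#' @export
print.case_set <- function(x, ...) {
  cat(sprintf("<case_set> %s: %d case(s)", x$query$canonical_name,
              nrow(x$cases)))
  if (!is.null(x$events))
    cat(sprintf(", %d distinct case-PT pair(s) (%d PT(s) in signal set)",
                nrow(x$events), length(unique(x$events$pt[x$events$in_signal]))))
  cat("\n")
  invisible(x)
}
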