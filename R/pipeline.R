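# End-to-end orchestration: simulate (or read) -> deduplicate -> select ->
# contingency -> four-algorithm signals -> time-to-onset, for each
# configured drug, with cross-drug comparison and a reproducibility
# manifest.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate data from `synth`), `"faers"` (read a
#'   quarter from `dir`), or `"jader"` (read JADER-style tables from `dir`).
#' @param drugs list of [drug_query()] objects to analyse. For synthetic
#'   mode the default analyses every generated drug.
#' @param synth a [synth_config()] (synthetic mode).
#' @param dir,quarter_tag input location (file modes).
#' @param term_map data.frame (`pt`, `soc`) or path to a TSV; synthetic mode
#'   defaults to [synth_term_map()].
#' @param min_count minimum target count for a term to enter signal
#'   analysis.
#' @param thresholds a [pv_thresholds()] list.
#' @param sensitivity also run the monotherapy sensitivity analysis
#'   ([exclude_concomitant()]).
#' @param exclude_indication_pts drop PTs that equal a case indication from
#'   the signal tables (the indication itself is not an adverse event);
#'   `TRUE` uses each drug's reported indications, or supply a character
#'   vector of PTs.
#' @param out_dir when non-`NULL`, TSV outputs and a JSON manifest are
#'   written there.
#' @return a list of class `pv_config`.
#' @export
pv_config <- function(mode = c("synthetic", "faers", "jader"),
                      drugs = NULL, synth = synth_config(),
                      dir = NULL, quarter_tag = "24Q2", term_map = NULL,
                      min_count = 3L, thresholds = pv_thresholds(),
                      sensitivity = FALSE, exclude_indication_pts = TRUE,
                      out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode != "synthetic" && is.null(dir))
    stop(sprintf("mode '%s' requires an input directory", mode))
  if (mode != "synthetic" && is.null(term_map))
    stop(sprintf("mode '%s' requires a term map", mode))
  if (mode != "synthetic" && is.null(drugs))
    stop(sprintf("mode '%s' requires explicit drug queries", mode))
  structure(list(mode = mode, drugs = drugs, synth = synth, dir = dir,
                 quarter_tag = quarter_tag, term_map = term_map,
                 min_count = as.integer(min_count),
                 thresholds = thresholds, sensitivity = sensitivity,
                 exclude_indication_pts = exclude_indication_pts,
                 out_dir = out_dir),
            class = "pv_config")
}

#' Run the full signal-detection pipeline
#'
#' Executes every stage for each configured drug: ingestion (or synthetic
#' generation with duplicate/deletion injection), deduplication and
#' deleted-case removal, target-drug case selection, demographic summary,
#' PT- and SOC-level contingency tables, four-algorithm disproportionality
#' statistics with Bonferroni correction, volcano table, overall
#' time-to-onset summary with Weibull fit, and (optionally) the monotherapy
#' sensitivity analysis. With two or more drugs it adds the SOC composition
#' chi-squared and the overlap of positive PT signals between the first two
#' drugs.
#'
#' @param config a [pv_config()].
#' @return a list with elements `drugs` (per-drug results), `overlap`,
#'   `composition`, `manifest`, and for synthetic mode `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pv_config"))
  truth <- NULL
  if (config$mode == "synthetic") {
    gen <- generate_reports(config$synth)
    inj <- inject_versions_and_deletions(gen$tables, gen$truth,
                                         config$synth)
    tables <- inj$tables
    truth <- inj$truth
    term_map <- config$term_map %||% synth_term_map(config$synth)
    drugs <- config$drugs %||%
      lapply(synth_drug_names(config$synth$n_drugs), drug_query)
  } else {
    tables <- if (config$mode == "faers")
      read_faers_quarter(config$dir, config$quarter_tag)
    else read_jader(config$dir)
    term_map <- config$term_map
    if (is.character(term_map)) term_map <- read_term_map(term_map)
    drugs <- config$drugs
  }

  survivors <- suppressWarnings(deduplicate(tables$demo))
  n_unparseable <- attr(survivors, "n_excluded")
  survivors <- apply_deletions(survivors, tables$demo, tables$deleted)
  pairs <- all_case_events(tables, term_map, survivors)

  per_drug <- lapply(drugs, function(q) {
    run_one_drug(q, tables, survivors, pairs, term_map, config)
  })
  names(per_drug) <- vapply(drugs, `[[`, "", "canonical_name")

  overlap <- NULL
  composition <- NULL
  if (length(per_drug) >= 2L) {
    s1 <- per_drug[[1]]$signals_pt
    s2 <- per_drug[[2]]$signals_pt
    if (!is.null(s1) && !is.null(s2))
      overlap <- compare_drugs(s1, s2)
    c1 <- per_drug[[1]]$soc_counts
    c2 <- per_drug[[2]]$soc_counts
    socs <- union(names(c1), names(c2))
    m1 <- ifelse(is.na(c1[socs]), 0L, c1[socs])
    m2 <- ifelse(is.na(c2[socs]), 0L, c2[socs])
    keep <- (m1 + m2) > 0
    if (sum(keep) >= 2L && sum(m1[keep]) > 0 && sum(m2[keep]) > 0)
      composition <- composition_chi2(m1[keep], m2[keep])
  }

  manifest <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    mode = config$mode,
    seed = if (config$mode == "synthetic") config$synth$seed else NULL,
    inputs = if (config$mode != "synthetic")
      as.list(tools::md5sum(list.files(config$dir, full.names = TRUE))),
    min_count = config$min_count,
    thresholds = unclass(config$thresholds),
    dedup = list(n_demo_rows = nrow(tables$demo),
                 n_survivors = length(survivors),
                 n_unparseable_fda_dt = n_unparseable,
                 n_deleted_listed = length(tables$deleted)),
    drugs = lapply(per_drug, function(r)
      list(n_cases = nrow(r$caseset$cases),
           n_terms_pt = if (!is.null(r$signals_pt)) nrow(r$signals_pt)
           else 0L,
           n_positive_pt = if (!is.null(r$signals_pt))
             sum(r$signals_pt$positive) else 0L))
  )

  result <- list(drugs = per_drug, overlap = overlap,
                 composition = composition, manifest = manifest,
                 truth = truth)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

run_one_drug <- function(query, tables, survivors, pairs, term_map,
                         config) {
  cs <- select_drug_cases(tables, query, survivors)
  if (!nrow(cs$cases))
    return(list(caseset = cs, demographics = NULL, signals_pt = NULL,
                signals_soc = NULL, volcano = NULL, tto = NULL,
                weibull = NULL, soc_counts = integer()))
  cs <- suppressWarnings(attach_events(cs, tables$reac, term_map,
                                       config$min_count))
  if (isTRUE(config$sensitivity)) cs <- exclude_concomitant(cs)
  demographics <- summarize_demographics(cs)

  exclude_pts <- character()
  if (isTRUE(config$exclude_indication_pts))
    exclude_pts <- unique(cs$cases$indication[nzchar(cs$cases$indication)])
  else if (is.character(config$exclude_indication_pts))
    exclude_pts <- config$exclude_indication_pts

  target_ids <- cs$cases$caseid
  tables_for <- function(level) {
    ct <- tryCatch(build_contingency(pairs, target_ids, level,
                                     config$min_count,
                                     drug = query$canonical_name),
                   error = function(e) NULL)
    if (is.null(ct) || !nrow(ct)) return(NULL)
    if (level == "PT" && length(exclude_pts))
      ct <- ct[!(ct$term %in% exclude_pts), , drop = FALSE]
    if (!nrow(ct)) return(NULL)
    ct
  }
  ct_pt <- tables_for("PT")
  ct_soc <- tables_for("SOC")
  # one empirical-Bayes prior per drug, fitted on the (richer) PT tables
  # and shared with the SOC level
  prior <- if (!is.null(ct_pt) && nrow(ct_pt) >= 2L)
    fit_gps_prior(ct_pt) else NULL
  signals_pt <- if (!is.null(ct_pt))
    signal_stats(ct_pt, prior = prior, thresholds = config$thresholds)
  signals_soc <- if (!is.null(ct_soc))
    signal_stats(ct_soc, prior = prior, thresholds = config$thresholds)

  soc_pairs <- unique(df0(caseid = pairs$caseid, soc = pairs$soc))
  soc_counts <- table(soc_pairs$soc[soc_pairs$caseid %in% target_ids])
  soc_counts <- stats::setNames(as.integer(soc_counts), names(soc_counts))

  tto <- compute_tto(cs, by = "overall")
  weib <- if (nrow(tto) >= 10L &&
              length(unique(pmax(tto$days, 0.5))) >= 2L)
    fit_weibull(tto) else NULL

  list(caseset = cs, demographics = demographics,
       signals_pt = signals_pt, signals_soc = signals_soc,
       volcano = if (!is.null(signals_pt))
         suppressWarnings(volcano_table(signals_pt)),
       tto = tto, tto_summary = if (nrow(tto)) tto_summary(tto),
       weibull = weib, soc_counts = soc_counts)
}

#' Overlap of positive signals between two drugs
#'
#' Set intersection and differences of the positive terms of two signal
#' tables computed at the same level, with both drugs' key statistics side
#' by side for the shared terms.
#'
#' @param stats_a,stats_b [signal_stats()] results at the same level.
#' @return list with `overlap` (data.frame of shared positive terms),
#'   `only_a`, `only_b` (character vectors).
#' @export
compare_drugs <- function(stats_a, stats_b) {
  if (!identical(unique(stats_a$level), unique(stats_b$level)))
    stop("signal tables were computed at different levels")
  pos_a <- stats_a$term[stats_a$positive]
  pos_b <- stats_b$term[stats_b$positive]
  shared <- intersect(pos_a, pos_b)
  ia <- match(shared, stats_a$term)
  ib <- match(shared, stats_b$term)
  list(
    overlap = df0(term = shared,
                  drug_a = if (length(shared)) stats_a$drug[ia]
                  else character(),
                  a_a = stats_a$a[ia], ror_a = stats_a$ror[ia],
                  ebgm_a = stats_a$ebgm[ia],
                  drug_b = if (length(shared)) stats_b$drug[ib]
                  else character(),
                  a_b = stats_b$a[ib], ror_b = stats_b$ror[ib],
                  ebgm_b = stats_b$ebgm[ib]),
    only_a = setdiff(pos_a, pos_b),
    only_b = setdiff(pos_b, pos_a)
  )
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

write_pipeline_outputs <- function(result, config) {
  out <- config$out_dir
  if (!dir.exists(out) &&
      !dir.create(out, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out)
  for (nm in names(result$drugs)) {
    r <- result$drugs[[nm]]
    safe <- gsub("[^A-Za-z0-9_-]", "_", nm)
    if (!is.null(r$demographics))
      write_tsv(r$demographics,
                file.path(out, sprintf("demographics_%s.tsv", safe)))
    if (!is.null(r$signals_pt))
      write_tsv(r$signals_pt,
                file.path(out, sprintf("signals_%s_PT.tsv", safe)))
    if (!is.null(r$signals_soc))
      write_tsv(r$signals_soc,
                file.path(out, sprintf("signals_%s_SOC.tsv", safe)))
    if (!is.null(r$volcano))
      write_tsv(r$volcano, file.path(out, sprintf("volcano_%s.tsv", safe)))
    if (!is.null(r$tto)) {
      write_tsv(r$tto, file.path(out, sprintf("tto_%s.tsv", safe)))
      write_tsv(attr(r$tto, "exclusions"),
                file.path(out, sprintf("tto_exclusions_%s.tsv", safe)))
    }
  }
  if (!is.null(result$overlap))
    write_tsv(result$overlap$overlap, file.path(out, "overlap.tsv"))
  jsonlite::write_json(result$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out)
}
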