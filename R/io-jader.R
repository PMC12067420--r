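# JADER-style tables: comma-delimited UTF-8 DEMO/DRUG/REAC/HIST files.
#
# JADER has no PRIMARYID/FDA_DT; the case identification key plays the
# CASEID role and each (case, report) carries a report identifier and report
# date. Therapy start dates and the event onset date both travel on the DRUG
# rows (the JADER convention), and the drug role codes are the Japanese
# terms. The canonical column map used here:
#
#   demo.csv: case_id, report_id, report_date, age, age_unit, sex, weight,
#             reporter, country, outcomes   (outcomes = ";"-joined codes)
#   drug.csv: report_id, drug_seq, role, drugname, start_dt, end_dt,
#             event_dt, indication         (role in Japanese, see below)
#   reac.csv: report_id, pt
#   hist.csv: report_id, condition         (optional; may be absent/empty)

JADER_ROLE_TO_CANON <- c(
  "被疑薬" = "PS",                       # suspected drug
  "被疑薬(二次)" = "SS",         # secondary suspect
  "併用薬" = "C",                        # concomitant
  "相互作用" = "I"                   # interaction
)
CANON_ROLE_TO_JADER <- stats::setNames(names(JADER_ROLE_TO_CANON),
                                       JADER_ROLE_TO_CANON)

jader_file_names <- function() {
  c(demo = "demo.csv", drug = "drug.csv", reac = "reac.csv",
    hist = "hist.csv")
}

#' Write report tables in the JADER-style layout
#'
#' Serializes a canonical [raw_report_tables()] object as four comma-
#' delimited UTF-8 files (DEMO, DRUG, REAC, HIST). The event onset date and
#' the therapy start date are written on the DRUG rows, role codes are the
#' Japanese terms, and per-case outcome codes are collapsed onto the DEMO
#' row. [read_jader()] on the output reconstructs the canonical tables.
#'
#' @param tables a [raw_report_tables()] object.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the named vector of written file paths.
#' @export
write_jader_tables <- function(tables, out_dir) {
  stopifnot(inherits(tables, "raw_report_tables"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- stats::setNames(file.path(out_dir, jader_file_names()),
                           names(jader_file_names()))

  outcomes <- vapply(tables$demo$primaryid, function(pid) {
    codes <- tables$outc$outc_cod[tables$outc$primaryid == pid]
    paste(sort(codes), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  demo <- df0(case_id = tables$demo$caseid,
              report_id = tables$demo$primaryid,
              report_date = tables$demo$fda_dt,
              age = tables$demo$age, age_unit = tables$demo$age_cod,
              sex = tables$demo$sex, weight = tables$demo$wt,
              reporter = tables$demo$occp_cod,
              country = tables$demo$reporter_country,
              outcomes = outcomes)

  drug <- tables$drug
  key <- paste(drug$primaryid, drug$drug_seq)
  ther_key <- paste(tables$ther$primaryid, tables$ther$dsg_drug_seq)
  ti <- match(key, ther_key)
  indi_key <- paste(tables$indi$primaryid, tables$indi$indi_drug_seq)
  ii <- match(key, indi_key)
  is_ps <- drug$role_cod == "PS"
  event_dt <- ifelse(is_ps,
                     tables$demo$event_dt[match(drug$primaryid,
                                                tables$demo$primaryid)],
                     "")
  role <- unname(CANON_ROLE_TO_JADER[drug$role_cod])
  role[is.na(role)] <- drug$role_cod[is.na(role)]
  jdrug <- df0(report_id = drug$primaryid, drug_seq = drug$drug_seq,
               role = role, drugname = drug$drugname,
               start_dt = ifelse(is.na(ti), "", tables$ther$start_dt[ti]),
               end_dt = ifelse(is.na(ti), "", tables$ther$end_dt[ti]),
               event_dt = event_dt,
               indication = ifelse(is.na(ii), "", tables$indi$indi_pt[ii]))

  jreac <- df0(report_id = tables$reac$primaryid, pt = tables$reac$pt)
  jhist <- df0(report_id = character(), condition = character())

  for (nm in names(paths)) {
    tb <- switch(nm, demo = demo, drug = jdrug, reac = jreac, hist = jhist)
    utils::write.csv(tb, paths[[nm]], row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  # deleted-case list is not part of the JADER layout; carry it alongside
  if (length(tables$deleted)) {
    del <- file.path(out_dir, "deleted.txt")
    writeLines(tables$deleted, del, useBytes = TRUE)
    paths <- c(paths, deleted = del)
  }
  invisible(paths)
}

read_jader_csv <- function(path, expected_cols, optional = FALSE) {
  if (!file.exists(path)) {
    if (optional)
      return(as.data.frame(stats::setNames(rep(list(character()),
                                               length(expected_cols)),
                                           expected_cols),
                           stringsAsFactors = FALSE))
    stop("file not found: ", path)
  }
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    if (optional)
      return(as.data.frame(stats::setNames(rep(list(character()),
                                               length(expected_cols)),
                                           expected_cols),
                           stringsAsFactors = FALSE))
  }
  tb <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(expected_cols, names(tb))
  if (length(missing_cols))
    stop(sprintf("%s: missing mandatory column(s): %s", basename(path),
                 paste(missing_cols, collapse = ", ")))
  tb
}

#' Read JADER-style tables into the canonical layout
#'
#' Maps the four JADER files onto [raw_report_tables()]: the case
#' identification key becomes `caseid`, the report identifier becomes
#' `primaryid`, the report date plays the `fda_dt` role for deduplication,
#' the event onset date is lifted from the primary-suspect DRUG row into
#' DEMO, and DRUG rows with a therapy start date yield THER rows. A missing
#' or empty HIST file is accepted.
#'
#' @param dir directory holding `demo.csv`, `drug.csv`, `reac.csv` and
#'   optionally `hist.csv` / `deleted.txt`.
#' @return a [raw_report_tables()] object.
#' @export
read_jader <- function(dir = ".") {
  paths <- stats::setNames(file.path(dir, jader_file_names()),
                           names(jader_file_names()))
  demo <- read_jader_csv(paths[["demo"]],
                         c("case_id", "report_id", "report_date", "age",
                           "age_unit", "sex", "weight", "reporter",
                           "country", "outcomes"))
  drug <- read_jader_csv(paths[["drug"]],
                         c("report_id", "drug_seq", "role", "drugname",
                           "start_dt", "end_dt", "event_dt", "indication"))
  reac <- read_jader_csv(paths[["reac"]], c("report_id", "pt"))
  read_jader_csv(paths[["hist"]], c("report_id", "condition"),
                 optional = TRUE)  # parsed for validity; unused downstream

  role <- unname(JADER_ROLE_TO_CANON[drug$role])
  role[is.na(role)] <- drug$role[is.na(role)]
  is_ps <- role == "PS"
  ev <- drug$event_dt[is_ps][match(demo$report_id, drug$report_id[is_ps])]
  ev[is.na(ev)] <- ""

  canon_demo <- df0(primaryid = demo$report_id, caseid = demo$case_id,
                    fda_dt = demo$report_date, event_dt = ev,
                    age = demo$age, age_cod = demo$age_unit, sex = demo$sex,
                    wt = demo$weight, reporter_country = demo$country,
                    occp_cod = demo$reporter)
  canon_drug <- df0(primaryid = drug$report_id, drug_seq = drug$drug_seq,
                    role_cod = role, drugname = drug$drugname)
  canon_reac <- df0(primaryid = reac$report_id, pt = reac$pt)

  has_out <- nzchar(demo$outcomes)
  codes <- strsplit(demo$outcomes[has_out], ";", fixed = TRUE)
  canon_outc <- df0(primaryid = rep(demo$report_id[has_out],
                                    lengths(codes)),
                    outc_cod = unlist(codes, use.names = FALSE) %||%
                      character())
  if (!nrow(canon_outc))
    canon_outc <- df0(primaryid = character(), outc_cod = character())

  has_ther <- nzchar(drug$start_dt)
  canon_ther <- df0(primaryid = drug$report_id[has_ther],
                    dsg_drug_seq = drug$drug_seq[has_ther],
                    start_dt = drug$start_dt[has_ther],
                    end_dt = drug$end_dt[has_ther])
  has_indi <- nzchar(drug$indication)
  canon_indi <- df0(primaryid = drug$report_id[has_indi],
                    indi_drug_seq = drug$drug_seq[has_indi],
                    indi_pt = drug$indication[has_indi])

  del_path <- file.path(dir, "deleted.txt")
  deleted <- if (file.exists(del_path)) {
    d <- readLines(del_path, encoding = "UTF-8", warn = FALSE)
    d[nzchar(trimws(d))]
  } else character()

  raw_report_tables(demo = canon_demo, drug = canon_drug, reac = canon_reac,
                    outc = canon_outc, ther = canon_ther, indi = canon_indi,
                    deleted = deleted)
}
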