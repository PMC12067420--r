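# The canonical parsed-report container shared by the FAERS and JADER
# readers and by the synthetic generator.

FAERS_COLUMNS <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "wt", "reporter_country", "occp_cod"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTCOME_CODES <- c("DE", "HO", "LT", "DS", "CA", "RI", "OT")
# most to least serious; used to pick one outcome per case
OUTCOME_SEVERITY <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Construct a raw report-table collection
#'
#' Bundles the six record tables of a quarterly spontaneous-report extract
#' (DEMO, DRUG, REAC, OUTC, THER, INDI) plus the deleted-case list into one
#' validated object. All fields are kept as text; dates are validated later,
#' at the point of use.
#'
#' @param demo,drug,reac,outc,ther,indi data.frames with the canonical
#'   lower-case columns (see `pvsignal:::FAERS_COLUMNS`).
#' @param deleted character vector of deleted CASEIDs.
#' @return an object of class `raw_report_tables`.
#' @export
raw_report_tables <- function(demo, drug, reac, outc, ther, indi,
                              deleted = character()) {
  x <- list(demo = demo, drug = drug, reac = reac, outc = outc, ther = ther,
            indi = indi, deleted = as.character(deleted))
  for (nm in names(FAERS_COLUMNS)) {
    missing_cols <- setdiff(FAERS_COLUMNS[[nm]], names(x[[nm]]))
    if (length(missing_cols))
      stop(sprintf("table '%s' lacks mandatory column(s): %s", nm,
                   paste(missing_cols, collapse = ", ")))
    x[[nm]] <- as.data.frame(lapply(x[[nm]][FAERS_COLUMNS[[nm]]],
                                    as.character),
                             stringsAsFactors = FALSE)
  }
  if (anyDuplicated(x$demo$primaryid))
    stop("primaryid must be unique within demo")
  for (nm in c("drug", "reac", "outc", "ther", "indi")) {
    orphan <- setdiff(x[[nm]]$primaryid, x$demo$primaryid)
    if (length(orphan))
      stop(sprintf("table '%s' has primaryid(s) absent from demo: %s", nm,
                   paste(utils::head(orphan, 5), collapse = ", ")))
  }
  structure(x, class = "raw_report_tables")
}

#' @export
print.raw_report_tables <- function(x, ...) {
  cat("<raw_report_tables>\n")
  for (nm in names(FAERS_COLUMNS))
    cat(sprintf("  %-5s %6d rows\n", nm, nrow(x[[nm]])))
  cat(sprintf("  deleted-case list: %d caseid(s)\n", length(x$deleted)))
  invisible(x)
}
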