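# Reading and writing FAERS-style "$"-delimited quarterly ASCII files.

faers_file_names <- function(quarter_tag) {
  c(stats::setNames(sprintf("%s%s.txt", toupper(names(FAERS_COLUMNS)),
                            quarter_tag),
                    names(FAERS_COLUMNS)),
    deleted = sprintf("DELETED%s.txt", quarter_tag))
}

#' Write report tables as a FAERS-style quarter
#'
#' One "$"-delimited file per table with a header row (`DEMO<tag>.txt`,
#' `DRUG<tag>.txt`, ...), plus a deleted-case list with one CASEID per line.
#' [read_faers_quarter()] on the output reproduces the input tables exactly.
#'
#' @param tables a [raw_report_tables()] object.
#' @param out_dir output directory (created if absent).
#' @param quarter_tag text appended to each file stem, e.g. `"24Q2"`.
#' @return invisibly, the named vector of written file paths.
#' @export
write_faers_quarter <- function(tables, out_dir, quarter_tag = "24Q2") {
  stopifnot(inherits(tables, "raw_report_tables"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  files <- faers_file_names(quarter_tag)
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  for (nm in names(FAERS_COLUMNS)) {
    tb <- tables[[nm]]
    lines <- c(paste(names(tb), collapse = "$"),
               if (nrow(tb)) do.call(paste, c(unname(tb), sep = "$")))
    writeLines(lines, paths[[nm]], useBytes = TRUE)
  }
  writeLines(tables$deleted, paths[["deleted"]], useBytes = TRUE)
  invisible(paths)
}

read_delim_table <- function(path, sep, expected_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("file is empty (no header row): ", path)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  missing_cols <- setdiff(expected_cols, header)
  if (length(missing_cols))
    stop(sprintf("%s: missing mandatory column(s): %s", basename(path),
                 paste(missing_cols, collapse = ", ")))
  body <- lines[-1]
  body <- body[nzchar(body) | seq_along(body) < length(body)]
  if (!length(body)) {
    out <- as.data.frame(stats::setNames(rep(list(character()),
                                             length(header)), header),
                         stringsAsFactors = FALSE)
    return(out)
  }
  # field count is 1 + number of separators (strsplit drops trailing empties)
  n_fields <- nchar(body) - nchar(gsub(sep, "", body, fixed = TRUE)) + 1L
  bad <- which(n_fields != length(header))
  if (length(bad))
    stop(sprintf("%s line %d: expected %d fields, found %d",
                 basename(path), bad[1] + 1L, length(header),
                 n_fields[bad[1]]))
  parts <- strsplit(body, sep, fixed = TRUE)
  parts <- lapply(parts, function(p)
    c(p, rep("", length(header) - length(p))))
  m <- matrix(unlist(parts, use.names = FALSE), ncol = length(header),
              byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- header
  out
}

#' Read a FAERS-style quarter
#'
#' Parses the "$"-delimited DEMO/DRUG/REAC/OUTC/THER/INDI files written by
#' [write_faers_quarter()] (or extracted from a public quarterly dump with
#' the canonical lower-case headers) plus the deleted-case list. Rows with
#' the wrong field count abort with the file name and line number; all
#' fields, including dates, are kept as text for later validation.
#'
#' @param dir directory holding the files.
#' @param quarter_tag tag used in the file names.
#' @param paths optional named character vector (`demo`, `drug`, `reac`,
#'   `outc`, `ther`, `indi`, `deleted`) overriding `dir`/`quarter_tag`.
#' @return a [raw_report_tables()] object.
#' @export
read_faers_quarter <- function(dir = ".", quarter_tag = "24Q2",
                               paths = NULL) {
  if (is.null(paths)) {
    files <- faers_file_names(quarter_tag)
    paths <- stats::setNames(file.path(dir, files), names(files))
  }
  tabs <- lapply(names(FAERS_COLUMNS), function(nm)
    read_delim_table(paths[[nm]], "$", FAERS_COLUMNS[[nm]]))
  names(tabs) <- names(FAERS_COLUMNS)
  deleted <- character()
  if (!is.null(paths[["deleted"]]) && file.exists(paths[["deleted"]])) {
    deleted <- readLines(paths[["deleted"]], encoding = "UTF-8", warn = FALSE)
    deleted <- deleted[nzchar(trimws(deleted))]
  }
  raw_report_tables(demo = tabs$demo, drug = tabs$drug, reac = tabs$reac,
                    outc = tabs$outc, ther = tabs$ther, indi = tabs$indi,
                    deleted = deleted)
}

#' Read a preferred-term to system-organ-class map
#'
#' Two-column tab-separated file, header `pt<TAB>soc` (case-insensitive;
#' a headerless two-column file is also accepted).
#'
#' @param path TSV path.
#' @return data.frame with columns `pt`, `soc`.
#' @export
read_term_map <- function(path) {
  tb <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(tb) != 2L) stop("term map must have exactly two columns (pt, soc)")
  if (!identical(tolower(names(tb)), c("pt", "soc"))) {
    # headerless file: first row was data
    tb <- rbind(names(tb), tb)
  }
  names(tb) <- c("pt", "soc")
  rownames(tb) <- NULL
  tb
}

#' Write a preferred-term to system-organ-class map
#'
#' @param term_map data.frame with columns `pt`, `soc`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_term_map <- function(term_map, path) {
  utils::write.table(term_map[c("pt", "soc")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
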