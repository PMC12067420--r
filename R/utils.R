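# Small shared helpers: date handling, rounding, RNG hygiene.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for report percentages so that
#' printed tables are reproducible independent of banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentages for a block of category counts
#'
#' Computes `100 * count / total` rounded half-up to one decimal, the
#' convention of spontaneous-report demographic tables.
#'
#' @param counts integer vector of category counts.
#' @param total denominator (defaults to `sum(counts)`).
#' @param digits decimal places (default 1).
#' @return numeric vector of percentages.
#' @export
#' @examples
#' case_proportion(c(12056, 2030), 35804)
case_proportion <- function(counts, total = sum(counts), digits = 1) {
  stopifnot(is.numeric(counts), length(total) == 1L, total > 0)
  round_half_up(100 * counts / total, digits)
}

# TRUE for strings that are valid 8-digit YYYYMMDD dates.
is_dt8 <- function(x) {
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  ok[ok] <- !is.na(as.Date(x[ok], format = "%Y%m%d"))
  ok
}

# Parse 8-digit date text to Date; NA where malformed.
parse_dt8 <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- is_dt8(x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

fmt_dt8 <- function(d) format(d, "%Y%m%d")

# Drug-name normalization: case-folded and trimmed, exact match only.
norm_drugname <- function(x) toupper(trimws(x))

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.frame without string factors or row names
df0 <- function(...) data.frame(..., stringsAsFactors = FALSE, row.names = NULL)
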