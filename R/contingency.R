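# 2x2 contingency tables: target drug x term against the all-other-drugs
# background, at PT or SOC level.
#
# For one term t and one target drug:
#   a = distinct (case, t) pairs among target-drug cases
#   b = target-drug event total - a
#   c = term total - a
#   d = n - a - b - c,  n = grand total of distinct (case, term) pairs.

#' Build 2x2 contingency tables for a target drug
#'
#' Counts distinct (case, term) pairs: a case contributes at most once per
#' term, and at SOC level at most once per SOC regardless of how many of
#' its PTs map there. The background is every other case in the same
#' dataset. One table is emitted per term whose target count `a` passes the
#' minimum-count filter.
#'
#' @param pairs data.frame of distinct case-term pairs over *all* retained
#'   cases, with columns `caseid`, `pt`, `soc` (see [all_case_events()]).
#' @param target_ids CASEIDs of the target drug's cases.
#' @param level `"PT"` or `"SOC"`.
#' @param min_count minimum target count `a` for a term to be tabulated
#'   (default 3).
#' @param drug label recorded on the output rows.
#' @return data.frame of class `contingency_tables` with columns
#'   `drug`, `level`, `term`, `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(pairs, target_ids, level = c("PT", "SOC"),
                              min_count = 3L, drug = "target") {
  level <- match.arg(level)
  term <- if (level == "PT") pairs$pt else pairs$soc
  pp <- unique(df0(caseid = pairs$caseid, term = term))
  if (nrow(pp) < 1L) stop("no case-term pairs to tabulate")
  if (length(unique(pp$term)) < 2L)
    stop("dataset must contain at least two distinct terms")
  is_target <- pp$caseid %in% target_ids
  if (!any(is_target)) stop("target drug absent from the dataset")
  if (all(is_target))
    stop("single-drug dataset: no background reports (c + d = 0)")

  n <- nrow(pp)
  target_total <- sum(is_target)
  term_tot <- table(pp$term)
  a_tab <- table(pp$term[is_target])
  terms <- names(a_tab)[as.integer(a_tab) >= min_count]
  if (!length(terms))
    return(structure(df0(drug = character(), level = character(),
                         term = character(), a = integer(), b = integer(),
                         c = integer(), d = integer(), n = integer()),
                     class = c("contingency_tables", "data.frame")))
  a <- as.integer(a_tab[terms])
  tt <- as.integer(term_tot[terms])
  b <- target_total - a
  cc <- tt - a
  d <- n - a - b - cc
  out <- df0(drug = drug, level = level, term = terms, a = a, b = b,
             c = cc, d = d, n = n)
  out <- out[order(-out$a, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contingency_tables", "data.frame"))
}

#' Expected count under independence
#'
#' `E = (a + b)(a + c) / n`, the expected target-drug count of a term if
#' drug and term were reported independently.
#'
#' @param ct a `contingency_tables` data.frame (or any frame with columns
#'   `a`, `b`, `c`, `n`).
#' @return numeric vector of expected counts.
#' @export
expected_count <- function(ct) {
  (ct$a + ct$b) * (ct$a + ct$c) / ct$n
}
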