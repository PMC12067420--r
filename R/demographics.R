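# Demographic and outcome summaries of a case set, in the layout of the
# standard "basic information" table of spontaneous-report studies.

# AGE with AGE_COD decoded to years; NA where unparseable.
decode_age_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  f <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18, DY = 1 / 365.25,
         HR = 1 / 8766)
  mult <- f[toupper(age_cod)]
  mult[is.na(mult) & !is.na(v)] <- 1  # blank unit with numeric age: years
  v * unname(mult)
}

age_band <- function(years) {
  band <- rep("Unknown", length(years))
  ok <- !is.na(years)
  band[ok & years < 18] <- "<18"
  band[ok & years >= 18 & years < 65] <- "18-65"
  band[ok & years >= 65 & years <= 85] <- "65-85"
  band[ok & years > 85] <- ">85"
  band
}

weight_band <- function(wt) {
  v <- suppressWarnings(as.numeric(wt))
  band <- rep("Unknown", length(v))
  ok <- !is.na(v)
  band[ok & v < 50] <- "<50"
  band[ok & v >= 50 & v <= 100] <- "50-100"
  band[ok & v > 100] <- ">100"
  band
}

count_block <- function(block, values, levels, total) {
  cnt <- table(factor(values, levels = levels))
  df0(block = block, category = levels, count = as.integer(cnt),
      percent = case_proportion(as.integer(cnt), total))
}

top_block <- function(block, values, total, k = 5) {
  values <- values[nzchar(values)]
  if (!length(values))
    return(df0(block = character(), category = character(),
               count = integer(), percent = numeric()))
  cnt <- sort(table(values), decreasing = TRUE)
  cnt <- utils::head(cnt, k)
  df0(block = block, category = names(cnt), count = as.integer(cnt),
      percent = case_proportion(as.integer(cnt), total))
}

#' Demographic and outcome summary of a case set
#'
#' Counts and percentages (percent = 100 * count / total, rounded half-up to
#' one decimal) for age bands (<18, 18-65, 65-85, >85, Unknown), sex, weight
#' bands, the top five reporting countries, reporter occupation category,
#' the top five indications, and serious-outcome codes (one most serious
#' code per case; `Missing` if none reported).
#'
#' @param caseset a `case_set` from [select_drug_cases()].
#' @return data.frame with columns `block`, `category`, `count`, `percent`.
#' @export
summarize_demographics <- function(caseset) {
  stopifnot(inherits(caseset, "case_set"))
  cs <- caseset$cases
  if (!nrow(cs)) stop("case set is empty")
  total <- nrow(cs)

  sexes <- rep("Unknown", total)
  sexes[cs$sex == "F"] <- "Female"
  sexes[cs$sex == "M"] <- "Male"

  occ <- ifelse(cs$occp_cod %in% c("CN", "HP", "LW", "MD", "OT", "PH"),
                cs$occp_cod, "Unknown")

  out <- rbind(
    count_block("age", age_band(decode_age_years(cs$age, cs$age_cod)),
                c("<18", "18-65", "65-85", ">85", "Unknown"), total),
    count_block("sex", sexes, c("Female", "Male", "Unknown"), total),
    count_block("weight", weight_band(cs$wt),
                c("<50", "50-100", ">100", "Unknown"), total),
    top_block("country", cs$reporter_country, total),
    count_block("reporter", occ,
                c("CN", "HP", "LW", "MD", "OT", "PH", "Unknown"), total),
    top_block("indication", cs$indication, total),
    count_block("outcome", cs$outcome, c(OUTCOME_SEVERITY, "Missing"),
                total)
  )
  rownames(out) <- NULL
  attr(out, "n_total") <- total
  out
}
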