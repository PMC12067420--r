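# Fixtures built in code: a hand-enumerable six-case dataset and shared
# small configurations.

# Six cases, two drugs, three PTs; every count checkable by hand.
tiny_tables <- function() {
  demo <- data.frame(
    primaryid = c("11", "21", "31", "41", "51", "61"),
    caseid = c("1", "2", "3", "4", "5", "6"),
    fda_dt = rep("20230401", 6),
    event_dt = c("20230110", "20230120", "", "20230215", "20230301",
                 "20230310"),
    age = c("70", "55", "", "80", "90", "17"),
    age_cod = c("YR", "YR", "", "YR", "YR", "YR"),
    sex = c("F", "M", "M", "F", "", "M"),
    wt = c("", "70", "", "", "110", "45"),
    reporter_country = c("US", "US", "UK", "US", "CA", "US"),
    occp_cod = c("CN", "MD", "", "PH", "CN", "MD"),
    stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = c("11", "21", "31", "41", "51", "61", "41"),
    drug_seq = c("1", "1", "1", "1", "1", "1", "2"),
    role_cod = c("PS", "PS", "PS", "PS", "PS", "PS", "C"),
    drugname = c("DRUG_A", "DRUG_A", "DRUG_A", "DRUG_B", "DRUG_B",
                 "DRUG_B", "OTHER"),
    stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = c("11", "11", "21", "31", "41", "51", "51", "61"),
    pt = c("PT_X", "PT_Y", "PT_X", "PT_Z", "PT_X", "PT_Y", "PT_Z",
           "PT_Z"),
    stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = c("11", "21", "21"),
                     outc_cod = c("DE", "HO", "DE"),
                     stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = c("11", "21", "41", "51", "61"),
                     dsg_drug_seq = c("1", "1", "1", "1", "1"),
                     start_dt = c("20230101", "20230115", "20230201",
                                  "202302", "20230401"),
                     end_dt = rep("", 5), stringsAsFactors = FALSE)
  indi <- data.frame(primaryid = "11", indi_drug_seq = "1",
                     indi_pt = "IND_1", stringsAsFactors = FALSE)
  raw_report_tables(demo = demo, drug = drug, reac = reac, outc = outc,
                    ther = ther, indi = indi)
}

tiny_term_map <- function() {
  data.frame(pt = c("PT_X", "PT_Y", "PT_Z"),
             soc = c("SOC_1", "SOC_1", "SOC_2"), stringsAsFactors = FALSE)
}

# A fixed, non-trivial gamma-mixture prior for estimator tests.
fixed_prior <- function() {
  structure(list(alpha1 = 0.3, beta1 = 0.25, alpha2 = 2, beta2 = 4,
                 p_mix = 0.4, loglik = NA_real_, n_tables = NA_integer_,
                 convergence = 0L),
            class = "gps_prior")
}

# A prior collapsed onto a single gamma component.
point_prior <- function(shape, rate) {
  structure(list(alpha1 = shape, beta1 = rate, alpha2 = shape,
                 beta2 = rate, p_mix = 1, loglik = NA_real_,
                 n_tables = NA_integer_, convergence = 0L),
            class = "gps_prior")
}

random_tables <- function(n, seed) {
  set.seed(seed)
  a <- rpois(n, exp(runif(n, 0, 5))) + 1L
  b <- rpois(n, 500) + 50L
  cc <- rpois(n, 300) + 30L
  d <- rpois(n, 50000) + 5000L
  data.frame(a = a, b = b, c = cc, d = d, n = a + b + cc + d,
             E = (a + b) * (a + cc) / (a + b + cc + d))
}
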