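# Synthetic report generator: ground-truth calibration, duplicate/deletion
# injection, and file-format round trips.

test_that("configuration invariants are enforced", {
  expect_error(synth_config(drug_weights = c(0.5, 0.6),  n_drugs = 2),
               "simplex")
  expect_error(synth_config(duplicate_rate = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(n_reports = 0), "n_reports")
  expect_error(
    synth_config(n_drugs = 2, n_events = 5,
                 planted_pairs = data.frame(drug = 3, event = 1, rr = 2)),
    "outside")
})

test_that("null model: observed pair counts match the multinomial expectation", {
  cfg <- synth_config(n_drugs = 5, n_events = 20, n_reports = 50000,
                      duplicate_rate = 0, deleted_rate = 0,
                      missing_event_date_rate = 0, concomitant_prob = 0,
                      seed = 101)
  gen <- generate_reports(cfg)
  tb <- gen$tables
  drug_of <- tb$drug$drugname[match(tb$demo$primaryid, tb$drug$primaryid)]
  pair <- table(drug = drug_of[match(tb$reac$primaryid, tb$demo$primaryid)],
                pt = tb$reac$pt)
  # oracle: P(PT in report) = 1 - E[(1-p)^k] with k ~ 1 + Poisson(mean),
  # via the pgf E[s^k] = s exp(mean (s - 1)); p uniform = 1/n_events
  p <- 1 / cfg$n_events
  p_incl <- 1 - (1 - p) * exp(cfg$events_per_report_mean * (-p))
  expected <- cfg$n_reports * cfg$drug_weights[1] * p_incl
  ratio <- as.vector(pair) / expected
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("a planted relative risk of 20 is recovered in the pair counts", {
  cfg <- synth_config(n_drugs = 5, n_events = 1000, n_reports = 20000,
                      duplicate_rate = 0, deleted_rate = 0,
                      planted_pairs = data.frame(drug = 2, event = 7,
                                                 rr = 20),
                      seed = 102)
  gen <- generate_reports(cfg)
  tb <- gen$tables
  target_pids <- tb$drug$primaryid[tb$drug$drugname == "DRUG_02" &
                                     tb$drug$role_cod == "PS"]
  a <- sum(tb$reac$pt == "PT_007" & tb$reac$primaryid %in% target_pids)
  # null multinomial expectation from the config weights
  e_null <- cfg$n_reports * cfg$drug_weights[2] *
    (1 + cfg$events_per_report_mean) / cfg$n_events
  expect_gt(a / e_null, 20 * 0.75)
  expect_lt(a / e_null, 20 * 1.25)
  # exact expectation under the planted configuration (distinct counts)
  p <- 20 / (cfg$n_events - 1 + 20)
  p_incl <- 1 - (1 - p) * exp(cfg$events_per_report_mean * (-p))
  e_exact <- cfg$n_reports * cfg$drug_weights[2] * p_incl
  expect_lt(abs(a / e_exact - 1), 0.15)
})

test_that("identical seeds give identical tables, different seeds differ", {
  cfg <- synth_config(n_reports = 300, seed = 5)
  g1 <- generate_reports(cfg)
  g2 <- generate_reports(cfg)
  expect_identical(g1, g2)
  cfg2 <- synth_config(n_reports = 300, seed = 6)
  expect_false(identical(generate_reports(cfg2)$tables$demo,
                         g1$tables$demo))
})

test_that("duplicate/deletion injection is truthful and recoverable", {
  cfg <- synth_config(n_reports = 1000, duplicate_rate = 0.1,
                      deleted_rate = 0.05, seed = 9)
  gen <- generate_reports(cfg)
  inj <- inject_versions_and_deletions(gen$tables, gen$truth, cfg)
  versions <- table(inj$tables$demo$caseid)
  expect_gte(sum(versions >= 2), 60)
  expect_lte(sum(versions >= 2), 140)
  # the ingest dedup recovers exactly the recorded survivor set
  surv <- deduplicate(inj$tables$demo)
  expect_setequal(surv, unname(inj$truth$survivors))
  # deleted list: non-empty, all listed CASEIDs exist in DEMO
  expect_gt(length(inj$tables$deleted), 0)
  expect_true(all(inj$tables$deleted %in% inj$tables$demo$caseid))
  expect_true(all(inj$truth$deleted_caseids %in%
                    inj$truth$canonical_caseids))
})

test_that("zero duplicate and deletion rates leave the tables unchanged", {
  cfg <- synth_config(n_reports = 200, duplicate_rate = 0,
                      deleted_rate = 0, seed = 2)
  gen <- generate_reports(cfg)
  inj <- inject_versions_and_deletions(gen$tables, gen$truth, cfg)
  expect_identical(inj$tables, gen$tables)
  expect_identical(inj$truth, gen$truth)
})

test_that("FAERS-style quarter round-trips field for field", {
  cfg <- synth_config(n_reports = 150, seed = 4)
  gen <- generate_reports(cfg)
  inj <- inject_versions_and_deletions(gen$tables, gen$truth, cfg)
  tb <- inj$tables
  tb$drug$drugname[1] <- "BLINDED PIRFENIDONE"  # space must survive
  d <- withr::local_tempdir()
  write_faers_quarter(tb, d, "24Q2")
  tb2 <- read_faers_quarter(d, "24Q2")
  expect_identical(unclass(tb)[names(tb)], unclass(tb2)[names(tb2)])
})

test_that("an empty REAC table round-trips as zero records", {
  cfg <- synth_config(n_reports = 20, seed = 4, duplicate_rate = 0,
                      deleted_rate = 0)
  tb <- generate_reports(cfg)$tables
  tb$reac <- tb$reac[0, , drop = FALSE]
  d <- withr::local_tempdir()
  write_faers_quarter(tb, d, "20Q1")
  tb2 <- read_faers_quarter(d, "20Q1")
  expect_identical(nrow(tb2$reac), 0L)
  expect_identical(names(tb2$reac), names(tb$reac))
})

test_that("JADER-style tables round-trip, including non-ASCII drug names", {
  cfg <- synth_config(n_reports = 120, seed = 8)
  gen <- generate_reports(cfg)
  inj <- inject_versions_and_deletions(gen$tables, gen$truth, cfg)
  tb <- inj$tables
  tb$drug$drugname[tb$drug$drugname == "DRUG_01"] <- "ピルフェニドン"
  d <- withr::local_tempdir()
  write_jader_tables(tb, d)
  tb2 <- read_jader(d)
  for (nm in c("demo", "drug", "reac", "ther", "indi"))
    expect_identical(tb2[[nm]], tb[[nm]])
  ord <- function(x) {
    x <- x[order(x$primaryid, x$outc_cod), , drop = FALSE]
    rownames(x) <- NULL
    x
  }
  expect_identical(ord(tb2$outc), ord(tb$outc))
  expect_identical(tb2$deleted, tb$deleted)
  expect_true("ピルフェニドン" %in% tb2$drug$drugname)
})

test_that("a missing HIST file is accepted on re-read", {
  cfg <- synth_config(n_reports = 30, seed = 1, duplicate_rate = 0,
                      deleted_rate = 0)
  tb <- generate_reports(cfg)$tables
  d <- withr::local_tempdir()
  write_jader_tables(tb, d)
  unlink(file.path(d, "hist.csv"))
  expect_silent(tb2 <- read_jader(d))
  expect_identical(tb2$demo, tb$demo)
})
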