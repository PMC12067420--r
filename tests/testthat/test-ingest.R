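# Deduplication, deletion, drug selection, event attachment and
# demographic summaries.

test_that("deduplication keeps the latest FDA_DT, then the higher PRIMARYID", {
  demo <- data.frame(
    caseid = c("1", "1", "2", "2", "3"),
    fda_dt = c("20230101", "20230301", "20230301", "20230301", "20230101"),
    primaryid = c("100", "90", "90", "100", "7"),
    stringsAsFactors = FALSE)
  surv <- deduplicate(demo)
  expect_setequal(as.character(surv), c("90", "100", "7"))
  expect_identical(as.character(surv[1]), "90")    # case 1: later FDA_DT wins
  expect_identical(as.character(surv[2]), "100")   # case 2: tie, higher id
})

test_that("rows with unparseable FDA_DT are excluded with a warning count", {
  demo <- data.frame(caseid = c("1", "2", "2"),
                     fda_dt = c("202301", "20230101", "bad"),
                     primaryid = c("10", "20", "30"),
                     stringsAsFactors = FALSE)
  expect_warning(surv <- deduplicate(demo), "2 DEMO row")
  expect_identical(as.character(surv), "20")
  expect_identical(attr(surv, "n_excluded"), 2L)
})

test_that("deduplication is idempotent and conserves distinct caseids", {
  cfg <- synth_config(n_reports = 800, duplicate_rate = 0.15,
                      deleted_rate = 0, seed = 12)
  gen <- generate_reports(cfg)
  inj <- inject_versions_and_deletions(gen$tables, gen$truth, cfg)
  demo <- inj$tables$demo
  surv <- deduplicate(demo)
  expect_length(surv, length(unique(demo$caseid)))
  again <- deduplicate(demo[demo$primaryid %in% surv, , drop = FALSE])
  expect_setequal(as.character(again), as.character(surv))
})

test_that("deleted-case handling removes exactly the listed survivors", {
  demo <- data.frame(caseid = c("1", "2", "3"),
                     fda_dt = rep("20230101", 3),
                     primaryid = c("10", "20", "30"),
                     stringsAsFactors = FALSE)
  surv <- deduplicate(demo)
  expect_identical(apply_deletions(surv, demo, character()), surv)
  kept <- apply_deletions(surv, demo, "1")
  expect_setequal(as.character(kept), c("20", "30"))
  expect_message(noop <- apply_deletions(surv, demo, "99"), "not present")
  expect_setequal(as.character(noop), as.character(surv))
})

test_that("drug selection matches normalized synonyms under the role filter", {
  tb <- tiny_tables()
  tb$drug$drugname[tb$drug$drugname == "DRUG_A"] <-
    c("ESBRIET", "  esbriet ", "Esbriet")
  cs <- select_drug_cases(tb, pirfenidone_query())
  expect_setequal(cs$cases$caseid, c("1", "2", "3"))
  # a case whose only match has role C is excluded under the PS default
  tb2 <- tiny_tables()
  tb2$drug$drugname[7] <- "ESBRIET"  # case 4, role C
  cs2 <- select_drug_cases(tb2, pirfenidone_query())
  expect_identical(nrow(cs2$cases), 0L)
  # but retained when the role filter admits concomitant rows
  cs3 <- select_drug_cases(tb2, drug_query("pirfenidone", "ESBRIET",
                                           roles = c("PS", "C")))
  expect_identical(cs3$cases$caseid, "4")
  expect_error(drug_query("x", character()), "non-empty")
})

test_that("concomitant counts and the sensitivity filter agree", {
  tb <- tiny_tables()
  cs <- select_drug_cases(tb, drug_query("B", "DRUG_B"))
  expect_setequal(cs$cases$caseid, c("4", "5", "6"))
  expect_identical(cs$cases$concomitant_drug_count[cs$cases$caseid == "4"],
                   1L)
  mono <- exclude_concomitant(cs)
  expect_setequal(mono$cases$caseid, c("5", "6"))
  expect_identical(nrow(exclude_concomitant(mono)$cases), 2L)
  cs0 <- cs
  cs0$cases <- cs0$cases[0, , drop = FALSE]
  expect_identical(nrow(exclude_concomitant(cs0)$cases), 0L)
})

test_that("event attachment applies the minimum-count filter and SOC map", {
  tb <- tiny_tables()
  cs <- select_drug_cases(tb, drug_query("A", "DRUG_A"))
  cs <- attach_events(cs, tb$reac, tiny_term_map(), min_count = 2)
  # PT_X occurs in cases 1 and 2 (count 2, in signal); PT_Y and PT_Z once
  ev <- cs$events
  expect_true(all(ev$in_signal[ev$pt == "PT_X"]))
  expect_false(any(ev$in_signal[ev$pt %in% c("PT_Y", "PT_Z")]))
  cs1 <- attach_events(cs, tb$reac, tiny_term_map(), min_count = 1)
  expect_true(all(cs1$events$in_signal))
  # unmapped PT goes to the UNMAPPED bucket with a warning
  expect_warning(
    csu <- attach_events(cs, rbind(tb$reac,
                                   data.frame(primaryid = "11",
                                              pt = "PT_NEW")),
                         tiny_term_map()),
    "UNMAPPED")
  expect_identical(csu$events$soc[csu$events$pt == "PT_NEW"], "UNMAPPED")
})

test_that("demographic percentages reproduce hand-computed proportions", {
  expect_identical(case_proportion(12056, 35804), 33.7)
  expect_identical(case_proportion(8130, 35804), 22.7)
  tb <- tiny_tables()
  cs <- select_drug_cases(tb, drug_query("A", "DRUG_A"))
  s <- summarize_demographics(cs)
  expect_identical(s$count[s$block == "age" & s$category == "65-85"], 1L)
  expect_identical(s$percent[s$block == "age" & s$category == "65-85"],
                   33.3)
  # a single case puts 100% in each of its categories
  one <- cs
  one$cases <- one$cases[1, , drop = FALSE]
  s1 <- summarize_demographics(one)
  expect_true(all(s1$percent[s1$count == 1L] == 100.0))
})

test_that("percentages over any partition block sum to about 100", {
  cfg <- synth_config(n_reports = 1500, seed = 21)
  gen <- generate_reports(cfg)
  cs <- select_drug_cases(gen$tables, drug_query("DRUG_03"))
  s <- summarize_demographics(cs)
  for (blk in c("age", "sex", "weight", "reporter", "outcome")) {
    expect_lt(abs(sum(s$percent[s$block == blk]) - 100), 0.3)
  }
})

test_that("the most serious outcome is kept when a case reports several", {
  tb <- tiny_tables()
  cs <- select_drug_cases(tb, drug_query("A", "DRUG_A"))
  # case 2 reports HO and DE; DE is the more serious
  expect_identical(cs$cases$outcome[cs$cases$caseid == "2"], "DE")
  expect_identical(cs$cases$outcome[cs$cases$caseid == "3"], "Missing")
})

test_that("malformed FAERS rows abort with file and line diagnostics", {
  cfg <- synth_config(n_reports = 10, seed = 1, duplicate_rate = 0,
                      deleted_rate = 0)
  tb <- generate_reports(cfg)$tables
  d <- withr::local_tempdir()
  paths <- write_faers_quarter(tb, d, "24Q2")
  lines <- readLines(paths[["reac"]])
  lines[3] <- paste0(lines[3], "$extra$fields")
  writeLines(lines, paths[["reac"]])
  expect_error(read_faers_quarter(d, "24Q2"), "REAC24Q2.txt line 3")
  # missing mandatory column
  writeLines(c("primaryid$nope", "1$x"), paths[["reac"]])
  expect_error(read_faers_quarter(d, "24Q2"), "mandatory column")
})

test_that("an empty deleted-list file reads back as an empty set", {
  cfg <- synth_config(n_reports = 10, seed = 1, duplicate_rate = 0,
                      deleted_rate = 0)
  tb <- generate_reports(cfg)$tables
  d <- withr::local_tempdir()
  write_faers_quarter(tb, d, "24Q2")
  expect_identical(read_faers_quarter(d, "24Q2")$deleted, character())
})

test_that("Japanese synonyms select JADER-style cases", {
  tb <- tiny_tables()
  tb$drug$drugname[1] <- "ピルフェニドン"
  d <- withr::local_tempdir()
  write_jader_tables(tb, d)
  tb2 <- read_jader(d)
  cs <- select_drug_cases(tb2, pirfenidone_query())
  expect_true("1" %in% cs$cases$caseid)
})
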