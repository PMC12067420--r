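# ROR, PRR + chi-squared, BCPNN, Bonferroni, positivity, composition and
# volcano tables, each against an independent evaluation.

test_that("ROR and its Wald interval match direct arithmetic", {
  r <- ror_stat(10, 90, 100, 900)
  expect_equal(r$ror, 1.0, tolerance = 1e-12)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 900)
  expect_equal(r$ror_l, exp(-1.96 * se), tolerance = 1e-9)
  expect_equal(r$ror_u, exp(+1.96 * se), tolerance = 1e-9)
  expect_equal(round(c(r$ror_l, r$ror_u), 3), c(0.504, 1.984))
  expect_equal(ror_stat(20, 80, 10, 890)$ror, 22.25, tolerance = 1e-9)
  # degenerate cells
  expect_true(is.na(ror_stat(5, 0, 10, 100)$ror))   # b = 0
  r0 <- ror_stat(0, 50, 10, 100)                     # a = 0
  expect_identical(r0$ror, 0)
  expect_true(is.na(r0$ror_l))
})

test_that("PRR and Pearson chi-squared match hand computation", {
  p <- prr_stat(10, 90, 100, 900)
  expect_equal(p$prr, 1.0, tolerance = 1e-12)
  expect_equal(p$chi2, 0, tolerance = 1e-12)
  p2 <- prr_stat(20, 80, 10, 890)
  expect_equal(p2$prr, 18.0, tolerance = 1e-9)
  chi_hand <- 1000 * (20 * 890 - 80 * 10)^2 /
    (100 * 900 * 30 * 970)
  expect_equal(p2$chi2, chi_hand, tolerance = 1e-9)
  expect_equal(round(p2$chi2, 2), 110.35)
  expect_equal(p2$p_raw, pchisq(chi_hand, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(is.na(prr_stat(5, 10, 0, 100)$prr))   # c = 0
  # Yates correction reduces the statistic
  expect_lt(prr_stat(20, 80, 10, 890, yates = TRUE)$chi2, p2$chi2)
})

test_that("BCPNN IC matches an independent closed-form evaluation", {
  # independent re-derivation of the posterior moments
  oracle <- function(a, b, c, d) {
    n <- a + b + c + d; n11 <- a; nd <- a + b; ne <- a + c
    g1 <- 1; a1 <- 1; b1 <- 1; aa <- 2; bb <- 2
    g <- g1 * (n + aa) * (n + bb) / ((nd + a1) * (ne + b1))
    eic <- (log((n11 + g1) * (n + aa) * (n + bb)) -
              log((n + g) * (nd + a1) * (ne + b1))) / log(2)
    vic <- ((n - n11 + g - g1) / ((n11 + g1) * (1 + n + g)) +
              (n - nd + aa - a1) / ((nd + a1) * (1 + n + aa)) +
              (n - ne + bb - b1) / ((ne + b1) * (1 + n + bb))) / log(2)^2
    c(ic = eic, ic025 = eic - 2 * sqrt(vic))
  }
  tabs <- random_tables(50, seed = 77)
  got <- bcpnn_stat(tabs$a, tabs$b, tabs$c, tabs$d)
  want <- t(mapply(oracle, tabs$a, tabs$b, tabs$c, tabs$d))
  expect_equal(got$ic, unname(want[, "ic"]), tolerance = 1e-9)
  expect_equal(got$ic025, unname(want[, "ic025"]), tolerance = 1e-9)
  expect_true(all(got$ic025 < got$ic))
  # independence limit
  expect_lt(abs(bcpnn_stat(1000, 9000, 9000, 81000)$ic), 0.02)
})

test_that("the independence null leaves all estimators near 1 (or 0 bits)", {
  # a family of tables with a exactly equal to its expectation
  mk <- function(a, f) {
    tot_d <- a * f; tot_e <- a * f; n <- a * f * f
    data.frame(a = a, b = tot_d - a, c = tot_e - a,
               d = n - tot_d - tot_e + a, n = n,
               E = a)
  }
  tabs <- do.call(rbind, lapply(c(100, 200, 500, 1000, 2000),
                                function(a) mk(a, 10)))
  tabs <- tabs[rep(1:5, each = 10), ]
  r <- ror_stat(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(abs(log(r$ror)) < 0.05))
  expect_true(all(abs(bcpnn_stat(tabs$a, tabs$b, tabs$c, tabs$d)$ic) < 0.05))
  pr <- suppressWarnings(fit_gps_prior(tabs))
  expect_gt(gps_prior_mean(pr), 0.8)
  expect_lt(gps_prior_mean(pr), 1.2)
  eb <- ebgm_stat(tabs$a, tabs$E, pr)
  expect_true(all(eb$ebgm > 0.8 & eb$ebgm < 1.2))
})

test_that("all four estimators are strictly increasing in a", {
  a <- c(5, 10, 20, 40, 80)
  r <- ror_stat(a, 500, 300, 50000)
  p <- prr_stat(a, 500, 300, 50000)
  ic <- bcpnn_stat(a, 500, 300, 50000)$ic
  E <- (a + 500) * (a + 300) / (a + 500 + 300 + 50000)
  eb <- ebgm_stat(a, E, fixed_prior())$ebgm
  expect_true(all(diff(r$ror) > 0))
  expect_true(all(diff(p$prr) > 0))
  expect_true(all(diff(ic) > 0))
  expect_true(all(diff(eb) > 0))
})

test_that("Bonferroni adjustment follows P-adjusted = P-original * n, capped", {
  expect_equal(bonferroni_adjust(0.0004, 100), 0.04)
  expect_lt(bonferroni_adjust(0.0004, 100), 0.05)   # significant
  expect_equal(bonferroni_adjust(0.001, 100), 0.1)  # not significant
  expect_equal(bonferroni_adjust(0.5, 100), 1.0)    # capped
  expect_equal(bonferroni_adjust(c(0.01, 0.2)), c(0.02, 0.4))
})

test_that("four-way positivity uses strict inequalities", {
  ct <- structure(
    data.frame(drug = "X", level = "PT", term = "t",
               a = 40L, b = 460L, c = 100L, d = 49400L,
               n = 50000L, stringsAsFactors = FALSE),
    class = c("contingency_tables", "data.frame"))
  ss <- suppressWarnings(signal_stats(ct, prior = fixed_prior()))
  expect_true(ss$positive)
  # move each threshold onto the attained value: strictness flips the flag
  on_l <- suppressWarnings(
    signal_stats(ct, prior = fixed_prior(),
                 thresholds = pv_thresholds(ror_ci_lower = ss$ror_l)))
  expect_false(on_l$flag_ror)
  on_ic <- suppressWarnings(
    signal_stats(ct, prior = fixed_prior(),
                 thresholds = pv_thresholds(ic025_min = ss$ic025)))
  expect_false(on_ic$flag_bcpnn)
  on_eb <- suppressWarnings(
    signal_stats(ct, prior = fixed_prior(),
                 thresholds = pv_thresholds(ebgm05_min = ss$ebgm05)))
  expect_false(on_eb$flag_mgps)
  # a below the minimum count is never positive
  ct$a <- 2L
  low <- suppressWarnings(signal_stats(ct, prior = fixed_prior()))
  expect_false(low$positive)
})

test_that("composition chi-squared matches hand Pearson computation", {
  expect_equal(composition_chi2(c(10, 20, 30), c(10, 20, 30))$chi2, 0,
               tolerance = 1e-12)
  # 2x2 input reproduces the PRR chi-squared on the same cells
  cc <- composition_chi2(c(20, 10), c(80, 890))
  expect_equal(cc$chi2, prr_stat(20, 80, 10, 890)$chi2, tolerance = 1e-9)
  # brute-force observed-vs-expected sum on {(30,10),(10,30)}
  h <- composition_chi2(c(30, 10), c(10, 30))
  expect_equal(h$chi2, 20, tolerance = 1e-9)
  expect_identical(h$df, 1L)
  expect_error(composition_chi2(c(0, 10), c(0, 5)), "zero marginal")
})

test_that("volcano coordinates are the log2 ROR and -log10 adjusted p", {
  s <- data.frame(term = c("t1", "t2", "t3"), ror = c(8, 2, NA),
                  p_adj = c(0.01, 1, 0.5),
                  positive = c(TRUE, FALSE, FALSE),
                  stringsAsFactors = FALSE)
  expect_warning(v <- volcano_table(s), "skipped")
  expect_equal(v$log2_ror[v$term == "t1"], 3)
  expect_equal(v$neg_log10_p_adj[v$term == "t1"], 2)
  expect_equal(v$neg_log10_p_adj[v$term == "t2"], 0)
  expect_false("t3" %in% v$term)
})
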