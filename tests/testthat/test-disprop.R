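test_that("contingency construction partitions records and cases correctly", {
  # one case with two qualifying PTs: record unit counts pairs, case unit cases
  rp <- make_reports(c("nivolumab", "other", "other"), "Nausea")
  rp$reactions <- data.frame(
    case_id = c("X000001", "X000001", "X000002", "X000003"),
    pt = c("Atrial fibrillation", "Cardiac arrest", "Nausea", "Atrial fibrillation"),
    stringsAsFactors = FALSE)
  events <- c("Atrial fibrillation", "Cardiac arrest")
  rec <- build_contingency(rp, "nivolumab", events, unit = "record")
  expect_equal(rec$a, 2)
  cas <- build_contingency(rp, "nivolumab", events, unit = "case")
  expect_equal(cas$a, 1)
  # partition completeness: cells sum to all units exactly once
  expect_equal(rec$a + rec$b + rec$c + rec$d, nrow(rp$reactions))
  expect_equal(cas$a + cas$b + cas$c + cas$d, n_cases(rp))

  # no target-drug reports: a = b = 0, background intact
  none <- build_contingency(rp, "avelumab", events, unit = "case")
  expect_equal(c(none$a, none$b), c(0, 0))
  expect_equal(none$c + none$d, n_cases(rp))

  # empty background is an instructive error
  all_nivo <- make_reports("nivolumab", "Atrial fibrillation")
  expect_error(build_contingency(all_nivo, "nivolumab", "Atrial fibrillation"),
               "background")
})

test_that("ROR matches the closed form and its GLM oracle", {
  r <- ror(contingency_table(10, 90, 100, 9900))
  expect_equal(r$ror, 11.0)
  # frozen from glm_or_oracle(10, 90, 100, 9900)
  expect_equal(r$ror_low, 5.559515, tolerance = 1e-6)
  expect_equal(r$ror_high, 21.76449, tolerance = 1e-6)
  expect_false(r$corrected)
  o <- glm_or_oracle(10, 90, 100, 9900)
  expect_equal(r$ror, unname(o["or"]), tolerance = 1e-9)
  expect_equal(r$ror_low, unname(o["low"]), tolerance = 1e-9)

  # zero cell: Haldane-Anscombe on all four cells, flagged
  rz <- ror(contingency_table(0, 90, 100, 9900))
  expect_true(rz$corrected)
  expect_equal(rz$ror, (0.5 * 9900.5) / (90.5 * 100.5), tolerance = 1e-12)
})

test_that("PRR and the Yates chi-square match their oracles", {
  p <- prr(contingency_table(10, 90, 100, 9900))
  expect_equal(p$prr, 10.0)
  # frozen from chisq.test(matrix(c(10,90,100,9900),2,byrow=TRUE), correct=TRUE)
  expect_equal(p$chi2, 66.32694, tolerance = 1e-6)
  expect_equal(prr(contingency_table(0, 5, 100, 9900))$prr, 0)
  inf <- prr(contingency_table(5, 5, 0, 9900))
  expect_true(is.infinite(inf$prr) && inf$infinite)
  expect_error(prr(contingency_table(0, 0, 1, 1)), "a \\+ b")
})

test_that("IC matches the stated formula and its posterior quantiles", {
  x <- ic(contingency_table(10, 90, 100, 9900))
  E <- 100 * 110 / 10100
  expect_equal(x$expected, E, tolerance = 1e-12)
  expect_equal(x$ic, log2(10.5 / (E + 0.5)), tolerance = 1e-12)
  expect_equal(x$ic, 2.7241, tolerance = 1e-4)
  # frozen from log2(qgamma(c(.025,.975), 10.5, rate = E + 0.5))
  expect_equal(x$ic_low, 1.693957, tolerance = 1e-6)
  expect_equal(x$ic_high, 3.480670, tolerance = 1e-6)

  # observed equal to expected at large counts: IC near 0
  big <- ic(contingency_table(1000, 9000, 9000, 81000))
  expect_lt(abs(big$ic), 0.01)
  # a = 0 with sizeable expectation: negative shrinkage IC
  expect_lt(ic(contingency_table(0, 100, 100, 800))$ic, 0)
})

test_that("closed forms agree with brute-force oracles over random tables", {
  tabs <- random_tables(1000, seed = 202)
  res <- faersvigil:::.signal_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs$a[i]; b <- tabs$b[i]; c <- tabs$c[i]; d <- tabs$d[i]
    expect_equal(res$prr[i], prr_oracle(a, b, c, d), tolerance = 1e-10)
    ct <- suppressWarnings(stats::chisq.test(matrix(c(a, b, c, d), 2,
                                                    byrow = TRUE)))
    expect_equal(res$chi2[i], unname(ct$statistic), tolerance = 1e-10)
    o <- log_or_oracle(a, b, c, d)
    expect_equal(res$ror[i], unname(o["or"]), tolerance = 1e-10)
    expect_equal(res$ror_low[i], unname(o["low"]), tolerance = 1e-10)
    expect_equal(res$ror_high[i], unname(o["high"]), tolerance = 1e-10)
  }
  # the iterative GLM oracle converges to ~1e-7; spot-check a subset
  idx <- seq(1, 1000, by = 20)
  for (i in idx) {
    o <- glm_or_oracle(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(res$ror[i], unname(o["or"]), tolerance = 1e-6)
    expect_equal(res$ror_low[i], unname(o["low"]), tolerance = 1e-6)
    expect_equal(res$ror_high[i], unname(o["high"]), tolerance = 1e-6)
  }
})

test_that("IC025 tracks the Monte-Carlo posterior within 0.15 log2-units", {
  tabs <- random_tables(200, seed = 303, max_cell = 2000)
  tabs <- tabs[tabs$a >= 5, ]
  res <- faersvigil:::.ic_vec(tabs$a, tabs$b, tabs$c, tabs$d)
  mc <- mapply(mc_ic025, tabs$a, tabs$b, tabs$c, tabs$d,
               MoreArgs = list(ndraw = 20000, seed = 7))
  expect_true(all(abs(res$ic_low - mc) < 0.15))
  expect_lt(stats::median(abs(res$ic_low - mc)), 0.02)
})

test_that("ROR, PRR and IC are strictly increasing in a; ROR scale-invariant", {
  b <- 50; c <- 80; d <- 5000
  a <- 1:60
  r <- faersvigil:::.ror_vec(a, b, c, d)
  p <- faersvigil:::.prr_vec(a, b, c, d)
  i <- faersvigil:::.ic_vec(a, b, c, d)
  expect_true(all(diff(r$ror) > 0))
  expect_true(all(diff(p$prr) > 0))
  expect_true(all(diff(i$ic) > 0))

  base <- ror(contingency_table(12, 40, 77, 3000))
  for (k in c(2, 5, 10)) {
    scaled <- ror(contingency_table(12 * k, 40 * k, 77 * k, 3000 * k))
    expect_equal(scaled$ror, base$ror, tolerance = 1e-12)
    expect_lt(scaled$ror_high - scaled$ror_low, base$ror_high - base$ror_low)
  }
})

test_that("composite signal flags follow the screening criteria", {
  df <- data.frame(n = c(341, 100, 2, 10, 10),
                   ror_low = c(1.20, 0.90, 2.0, 1.5, 0.8),
                   prr = c(1.3, 1.0, 2.0, 0.9, 1.4),
                   chi2 = c(28, 1, 50, 1, 5),
                   ic_low = c(0.27, -0.1, 1.0, -0.2, -0.4))
  fl <- evaluate_signal(df)
  expect_equal(fl$ror_signal, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(fl$prr_signal, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(fl$ic_signal, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fl$any_signal, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  # the minimum-case rule can be lifted from the IC clause
  fl2 <- evaluate_signal(df, signal_criteria(apply_min_cases_ic = FALSE))
  expect_equal(fl2$ic_signal, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # but any_signal still requires the minimum case count
  expect_equal(fl2$any_signal, fl$any_signal)
})

test_that("comparative ROR is symmetric under group exchange and null at equality", {
  rp <- make_reports(rep(c("a", "b"), each = 200),
                     rep(rep(c("Atrial fibrillation", "Nausea"), c(30, 170)), 2),
                     regimen_class = rep(c("A", "B"), each = 200))
  eq <- comparative_ror(rp, "A", "B", "Atrial fibrillation")
  expect_equal(eq$ror, 1)

  rp2 <- make_reports(rep(c("a", "b"), each = 200),
                      c(rep(c("Atrial fibrillation", "Nausea"), c(60, 140)),
                        rep(c("Atrial fibrillation", "Nausea"), c(20, 180))),
                      regimen_class = rep(c("A", "B"), each = 200))
  ab <- comparative_ror(rp2, "A", "B", "Atrial fibrillation")
  ba <- comparative_ror(rp2, "B", "A", "Atrial fibrillation")
  expect_equal(ab$ror, 1 / ba$ror, tolerance = 1e-12)
  expect_equal(ab$ror_low, 1 / ba$ror_high, tolerance = 1e-12)
  expect_error(comparative_ror(rp2, "A", "C", "Nausea"), "zero reports")
})

test_that("the signal spectrum flags a planted pair and omits empty cells", {
  cfg <- synthetic_config(
    n_reports = 4000, seed = 314,
    drugs = data.frame(substance = c("nivolumab", "ipilimumab", "carboplatin"),
                       prob = c(0.15, 0.05, 0.80)),
    multipliers = data.frame(substance = "nivolumab",
                             pt = "Atrial fibrillation", multiplier = 8),
    revision_rate = 0)
  sim <- simulate_reports(cfg)
  rp <- classify_regimens(sim$reports, strict = FALSE)
  spec <- signal_spectrum(rp)
  cell <- spec[spec$regimen == "nivolumab" & spec$pt == "Atrial fibrillation", ]
  expect_equal(nrow(cell), 1)
  expect_true(cell$any_signal)
  # cells with zero co-reports are absent from the long table and NA in the matrix
  m <- attr(spec, "ror025")
  absent <- is.na(m["nivolumab", ])
  expect_false(any(paste(spec$regimen, spec$pt) %in%
                     paste("nivolumab", names(absent)[absent])))
  # cells below the minimum case count carry no flags
  small <- spec[spec$n < 3, ]
  if (nrow(small)) expect_false(any(small$any_signal))
})
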