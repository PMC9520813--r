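test_that("relative risks and odds ratios match direct arithmetic", {
  t <- ref_table()
  rr <- rr_effects(t)
  expect_equal(rr$RR_s$point, 2)
  expect_equal(rr$RR_e$point, 3)
  expect_equal(rr$RR_se$point, 12)
  expect_equal(rr$RR_s$log_se,
               sqrt(1 / 20 - 1 / 200 + 1 / 10 - 1 / 200))

  or <- or_effects(t)
  expect_equal(or$OR_s$point, 3800 / 1800)
  expect_equal(or$OR_e$point, 5700 / 1700)
  expect_equal(or$OR_se$point, 28.5)
  expect_equal(or$OR_s$log_se, sqrt(1 / 10 + 1 / 190 + 1 / 20 + 1 / 180))

  u <- uniform_table()
  for (est in c(rr_effects(u), or_effects(u)))
    expect_equal(est$point, 1)
})

test_that("degenerate tables are rejected or flagged, not silently computed", {
  expect_error(two_by_four_table(1, 2, 3, -1, 5, 6, 7, 8), "non-negative")
  expect_error(two_by_four_table(0, 0, 0, 0, 0, 0, 0, 0), "positive")
  # no reference cases
  t0 <- two_by_four_table(0, 200, 20, 180, 30, 170, 120, 80)
  expect_error(rr_effects(t0), "reference")
  # empty exposed-case cell: flagged zero, not an error, for the RR path
  tz <- two_by_four_table(10, 190, 0, 200, 30, 170, 120, 80)
  rr <- rr_effects(tz)
  expect_equal(rr$RR_s$point, 0)
  expect_true("zero-numerator" %in% rr$RR_s$flags)
  # the OR path needs every cell of its 2x2
  expect_error(or_effects(tz), "zero cell")
  or_cc <- or_effects(tz, correct = TRUE)
  expect_true(or_cc$OR_s$point > 0)
  expect_true("continuity" %in% or_cc$OR_s$flags)
})

test_that("case-only ICR and its asymptotic variance", {
  k <- case_only_counts(10, 10, 10, 10)
  est <- icr_co(k)
  expect_equal(est$point, 1)
  expect_equal(est$log_se, sqrt(0.4))

  expect_equal(icr_co(case_only_counts(10, 20, 30, 120))$point, 2)

  expect_error(icr_co(case_only_counts(10, 0, 30, 120)), "\\(c\\)")
  expect_error(icr_co(case_only_counts(10, 20, 0, 120)), "\\(e\\)")
  # zero numerator flagged rather than fatal
  z <- icr_co(case_only_counts(0, 20, 30, 120))
  expect_equal(z$point, 0)
  expect_true("zero-numerator" %in% z$flags)
})

test_that("the full-sample S-E association factor and its orientation", {
  expect_equal(seor_cnc(ref_table())$point, 1)  # margins all equal
  t2 <- two_by_four_table(10, 90, 20, 80, 30, 70, 120, 30)
  est <- seor_cnc(t2)
  expect_equal(est$point, (100 * 100) / (100 * 150))
  expect_equal(est$conventional_or, 1 / est$point)
  expect_error(seor_cnc(two_by_four_table(0, 0, 20, 80, 30, 70, 120, 30)),
               "margin")
})

test_that("full-sample ICR on both scales and bases", {
  t <- ref_table()
  expect_equal(icr_cnc(t, "multiplicative", "RR")$point, 12 / (2 * 3))
  expect_equal(icr_cnc(t, "additive", "RR")$point, 12 - (2 + 3 - 1))
  or <- or_effects(t)
  expect_equal(icr_cnc(t, "multiplicative", "OR")$point,
               or$OR_se$point / (or$OR_s$point * or$OR_e$point))
  u <- uniform_table()
  expect_equal(icr_cnc(u, "multiplicative", "RR")$point, 1)
  expect_equal(icr_cnc(u, "additive", "RR")$point, 0)
  # additive estimate carries no interval
  expect_true(is.na(icr_cnc(t, "additive", "RR")$ci_low))
})

test_that("the bootstrap interval for the table ICR is seeded and sane", {
  t <- ref_table()
  b1 <- icr_cnc(t, "multiplicative", "RR", ci = "bootstrap",
                boot_reps = 500, seed = 42)
  b2 <- icr_cnc(t, "multiplicative", "RR", ci = "bootstrap",
                boot_reps = 500, seed = 42)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_lt(b1$ci_low, b1$point)
  expect_gt(b1$ci_high, b1$point)
})

test_that("control sampling reproduces the expected-fraction layout", {
  t <- ref_table()
  cc <- sample_case_control(t, 0.1)
  expect_equal(unlist(cc[c("b", "d", "f", "h")]),
               c(b = 19, d = 18, f = 17, h = 8))
  cc2 <- sample_case_control(two_by_four_table(1, 100, 1, 100, 1, 100, 1, 100),
                             0.1)
  expect_equal(unlist(cc2[c("b", "d", "f", "h")]),
               c(b = 10, d = 10, f = 10, h = 10))
  expect_warning(sample_case_control(t, 0.13), "non-integer")
  expect_error(sample_case_control(t, 0), "p must lie")
  expect_error(sample_case_control(t, 1.2), "p must lie")
  # binomial mode: seeded, reproducible, within range
  b1 <- sample_case_control(t, 0.3, mode = "binomial", seed = 9)
  b2 <- sample_case_control(t, 0.3, mode = "binomial", seed = 9)
  expect_identical(unlist(b1), unlist(b2))
  expect_true(all(unlist(b1[c("b", "d", "f", "h")]) <=
                  unlist(t[c("B", "D", "F", "H")])))
})

test_that("case-control ICR and the control-population factor", {
  t <- ref_table()
  cc <- sample_case_control(t, 0.1)
  expect_equal(icr_cc(cc)$point, 2 * (18 * 17) / (19 * 8))
  # equals the OR-basis full-sample ICR of the source table (p cancels)
  expect_equal(icr_cc(cc)$point, icr_cnc(t, basis = "OR")$point,
               tolerance = 1e-12)
  sc <- seor_control(cc)
  expect_equal(sc$point, 306 / 152)
  expect_equal(sc$conventional_or, 152 / 306)
  # balanced controls: ICR_cc collapses to the case-only ICR
  ccb <- case_control_table(10, 20, 30, 120, b = 10, d = 10, f = 10, h = 10)
  expect_equal(icr_cc(ccb)$point, icr_co(cases_of(t))$point)
  expect_equal(seor_control(ccb)$point, 1)
  expect_error(icr_cc(case_control_table(10, 20, 30, 120, 0, 10, 10, 10)),
               "zero cell")
})

test_that("the dependence correction reproduces the printed bound arithmetic", {
  co <- effect_estimate(1.14, ci_low = 1.03, ci_high = 1.37)
  se <- effect_estimate(1.06, ci_low = 1.03, ci_high = 1.10)
  adj <- adjust_icr(co, se, "bound_product")
  expect_equal(round(adj$point, 2), 1.21)
  expect_equal(round(adj$ci_low, 2), 1.06)
  expect_equal(round(adj$ci_high, 2), 1.51)

  # identity adjustment leaves the estimate untouched
  ident <- effect_estimate(1, 0)
  est <- effect_estimate(1.7, 0.1)
  adj2 <- adjust_icr(est, ident, "lognormal_sum")
  expect_equal(adj2$point, 1.7)
  expect_equal(adj2$log_se, 0.1)
  # reciprocal cancellation
  expect_equal(adjust_icr(effect_estimate(2, 0.1),
                          effect_estimate(0.5, 0.1))$point, 1)
  # quadrature variance, with log_se recovered from the CI when absent
  adj3 <- adjust_icr(co, se, "lognormal_sum")
  z <- qnorm(0.975)
  expect_equal(adj3$log_se,
               sqrt((log(1.37 / 1.03) / (2 * z))^2 +
                    (log(1.10 / 1.03) / (2 * z))^2))
  expect_error(adjust_icr(effect_estimate(0.5), effect_estimate(1)), NA)
})

test_that("the implied case-only ICR solves the identity in either orientation", {
  expect_equal(implied_case_only(2.5, 1)$point, 2.5)
  expect_equal(implied_case_only(1.0, 0.5)$point, 2.0)
  expect_equal(implied_case_only(1.0, 2.0, orientation = "conventional")$point,
               2.0)
  t <- ref_table()
  expect_equal(implied_case_only(icr_cnc(t, basis = "RR"), seor_cnc(t))$point,
               icr_co(cases_of(t))$point, tolerance = 1e-12)
})

test_that("design-relationship identities hold on random tables", {
  set.seed(421)
  for (i in 1:200) {
    t <- random_table()
    co <- icr_co(cases_of(t))$point
    seor <- seor_cnc(t)$point
    # full-sample ICR factorizes through the case-only ICR exactly
    expect_equal(icr_cnc(t, "multiplicative", "RR")$point, co * seor,
                 tolerance = 1e-12)
    # OR-basis ICR factorizes through the control-cell ratio
    expect_equal(icr_cnc(t, "multiplicative", "OR")$point,
                 co * (t$D * t$F) / (t$B * t$H), tolerance = 1e-12)
  }
})

test_that("the sampling fraction cancels out of the case-control ICR", {
  set.seed(422)
  for (i in 1:50) {
    # non-case counts divisible by 20 so expected-mode sampling is exact
    x <- sample(5:150, 4, replace = TRUE)
    nc <- 20 * sample(1:10, 4, replace = TRUE)
    t <- two_by_four_table(x[1], nc[1], x[2], nc[2], x[3], nc[3], x[4], nc[4])
    for (p in c(0.05, 0.25, 1)) {
      cc <- sample_case_control(t, p)
      expect_equal(icr_cc(cc)$point, icr_cnc(t, basis = "OR")$point,
                   tolerance = 1e-12)
      # case-control ICR re-expressed through the full-sample ICR
      expect_equal(icr_cc(cc)$point,
                   icr_cnc(t, basis = "RR")$point *
                     (t$D * t$F) / (t$B * t$H) *
                     ((t$a + t$B) * (t$g + t$H)) /
                     ((t$c + t$D) * (t$e + t$F)),
                   tolerance = 1e-12)
    }
  }
})

test_that("independence conditions collapse the estimators onto each other", {
  # balanced controls (df = bh): case-control ICR equals case-only ICR
  cc <- case_control_table(7, 21, 35, 140, b = 12, d = 24, f = 6, h = 12)
  expect_equal(seor_control(cc)$point, 1)
  expect_equal(icr_cc(cc)$point, icr_co(case_only_counts(7, 21, 35, 140))$point,
               tolerance = 1e-12)
  # equal full-sample margins (seor_cnc = 1): full-sample ICR = case-only ICR
  t <- ref_table()
  expect_equal(seor_cnc(t)$point, 1)
  expect_equal(icr_cnc(t, basis = "RR")$point, icr_co(cases_of(t))$point,
               tolerance = 1e-12)
})

test_that("RR- and OR-basis ICRs converge monotonically as the disease rarefies", {
  base <- list(a = 5, B = 100, c = 6, D = 120, e = 7, F = 140, g = 9, H = 150)
  gap <- sapply(c(1, 10, 100, 1000), function(lam) {
    t <- two_by_four_table(base$a, lam * base$B, base$c, lam * base$D,
                           base$e, lam * base$F, base$g, lam * base$H)
    abs(icr_cnc(t, basis = "RR")$point - icr_cnc(t, basis = "OR")$point)
  })
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[4], 1e-3)
  # the two S-E association factors converge in the same limit
  gap2 <- sapply(c(1, 10, 100, 1000), function(lam) {
    t <- two_by_four_table(base$a, lam * base$B, base$c, lam * base$D,
                           base$e, lam * base$F, base$g, lam * base$H)
    cc <- sample_case_control(t, 1)
    abs(seor_cnc(t)$point - seor_control(cc)$point)
  })
  expect_true(all(diff(gap2) < 0))
})

test_that("scaling all counts leaves points unchanged and shrinks variances", {
  set.seed(423)
  for (i in 1:20) {
    t <- random_table()
    t7 <- two_by_four_table(7 * t$a, 7 * t$B, 7 * t$c, 7 * t$D,
                            7 * t$e, 7 * t$F, 7 * t$g, 7 * t$H)
    expect_equal(icr_cnc(t7, basis = "RR")$point,
                 icr_cnc(t, basis = "RR")$point, tolerance = 1e-12)
    expect_equal(seor_cnc(t7)$point, seor_cnc(t)$point, tolerance = 1e-12)
    expect_equal(icr_co(cases_of(t7))$point, icr_co(cases_of(t))$point,
                 tolerance = 1e-12)
    expect_lt(icr_co(cases_of(t7))$log_se, icr_co(cases_of(t))$log_se)
    expect_lt(seor_cnc(t7)$log_se, seor_cnc(t)$log_se)
    expect_lt(or_effects(t7)$OR_se$log_se, or_effects(t)$OR_se$log_se)
  }
})
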