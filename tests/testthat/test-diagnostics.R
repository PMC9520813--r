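test_that("the rare-disease sensitivity formula matches direct substitution", {
  expect_equal(seor_control_sensitivity(0.3, 1, 1, 1, seor_cnc = 1), 1)
  expect_equal(seor_control_sensitivity(0.2, 1, 1, 3), (4 * 2) / (4 * 4))
  expect_equal(seor_control_sensitivity(0.2, 1, 1, 3, seor_cnc = 2), 1.0)
  expect_error(seor_control_sensitivity(0.5, 3, 1, 1), "domain")
  expect_error(seor_control_sensitivity(0, 1, 1, 1))
})

test_that("the control-population association converges to the full-sample one", {
  expect_lt(abs(seor_control_sensitivity(1e-6, 2, 1.5, 4) - 1), 1e-3)
  # monotone convergence over a log-spaced baseline grid
  gap <- sapply(10^seq(-1.5, -6, by = -0.5), function(p0)
    abs(seor_control_sensitivity(p0, 2.5, 1.5, 4, seor_cnc = 0.8) - 0.8))
  expect_true(all(diff(gap) < 0))
})

test_that("the sensitivity formula is exact on expected-table control cells", {
  # with S-E independence the conventional control odds ratio BH/DF equals
  # the sensitivity factor computed from the four stratum risks
  p <- sim_params(n = 10000, p_s = 0.3, p_e = 0.4, se_or = 1, beta0 = -2.5,
                  beta1 = log(2), beta2 = log(1.8), beta3 = log(1.3))
  t <- expected_table(p)
  r <- plogis(p$beta0 + p$beta1 * c(0, 1, 0, 1) + p$beta2 * c(0, 0, 1, 1) +
              p$beta3 * c(0, 0, 0, 1))
  expect_equal((t$B * t$H) / (t$D * t$F),
               seor_control_sensitivity(r[1], r[2] / r[1], r[3] / r[1],
                                        r[4] / r[1], seor_cnc = 1),
               tolerance = 1e-12)
})

test_that("the sensitivity grid covers the documented ranges", {
  g <- sensitivity_grid()
  expect_equal(nrow(g), 20)
  expect_setequal(unique(g$p0), c(0.001, 0.005, 0.01, 0.03, 0.06))
  expect_setequal(unique(g$rr_s), c(1, 1.5, 2.5, 4))
  expect_true(all(is.finite(g$seor_control)))
})

test_that("the analytic CIR and its degenerate cases", {
  expect_equal(cir(0.5, 0.4, 0.3), 1.06)
  expect_equal(cir(0, 0.7, 0.9), 1)
  expect_equal(cir(0.8, 0, 0.9), 1)
  expect_equal(cir(0.8, 0.7, 0), 1)
  expect_equal(cir(-0.5, 0.4, 0.3), 0.94)
  expect_error(cir(1.2, 0.4, 0.3))
  expect_error(cir(0.5, -0.1, 0.3))
})

test_that("the CIR bounds behave as the formula requires", {
  b <- cir_bounds(4, 4)
  expect_equal(unname(b["upper"]), 1.5625)
  expect_equal(unname(b["lower"]), 0.64)
  expect_equal(cir_bounds(1, 1), c(lower = 1, upper = 1))
  expect_equal(cir_bounds(1, 7), c(lower = 1, upper = 1))
  expect_equal(cir_bounds(9, 1), c(lower = 1, upper = 1))
  expect_error(cir_bounds(0.9, 2), ">= 1")
  set.seed(61)
  for (i in 1:50) {
    u <- 1 + rexp(2)
    b <- cir_bounds(u[1], u[2])
    expect_gte(unname(b["upper"]), 1)
    expect_equal(unname(b["upper"] * b["lower"]), 1, tolerance = 1e-12)
  }
})

test_that("the pooled S-E association induced by stratification respects the bounds", {
  # population-level check: mixing strata that are each S-E independent
  # induces a pooled association bounded by the odds-spread formula
  set.seed(62)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    p_s <- runif(k, 0.15, 0.7)
    p_e <- runif(k, 0.15, 0.7)
    w <- runif(k, 0.5, 2); w <- w / sum(w)
    pooled <- Reduce(`+`, lapply(seq_len(k), function(j)
      w[j] * joint_probs(p_s[j], p_e[j], 1)))
    pooled_or <- (pooled[4] * pooled[1]) / (pooled[2] * pooled[3])
    odds_s <- p_s / (1 - p_s); odds_e <- p_e / (1 - p_e)
    b <- cir_bounds(max(odds_s) / min(odds_s), max(odds_e) / min(odds_e))
    expect_gte(pooled_or, unname(b["lower"]) - 1e-12)
    expect_lte(pooled_or, unname(b["upper"]) + 1e-12)
  }
})

test_that("the first-order CIR prediction matches the induced association for modest spreads", {
  # two strata, equal sizes, odds spread ~30%: the pooled association is a
  # population quantity here, not a noisy fit
  p_s <- c(0.26, 0.34); p_e <- c(0.24, 0.31)
  pooled <- (joint_probs(p_s[1], p_e[1], 1) + joint_probs(p_s[2], p_e[2], 1)) / 2
  pooled_or <- (pooled[4] * pooled[1]) / (pooled[2] * pooled[3])
  odds_s <- p_s / (1 - p_s); odds_e <- p_e / (1 - p_e)
  pred <- cir(1, sd(odds_s) * sqrt(1 / 2) / mean(odds_s),
              sd(odds_e) * sqrt(1 / 2) / mean(odds_e))
  expect_equal(unname(pooled_or), pred, tolerance = 0.05 * (pred - 1) / pred + 0.01)
})

test_that("the empirical CIR isolates the case-only stratification bias", {
  params <- sim_params(n = c(60000, 60000), p_s = c(0.2, 0.5),
                       p_e = c(0.2, 0.5), se_or = 1, beta0 = -3.5,
                       beta3 = 0, seed = 63)
  res <- cir_empirical(simulate_population(params))
  # the pooled case-only estimate absorbs the induced association ...
  expect_gt(res$cir_empirical, 1.2)
  # ... while the stratum-adjusted case-only and both full-sample fits do not
  expect_true(abs(log(res$icr_co_stratified$point)) <
                3 * res$icr_co_stratified$log_se)
  expect_true(abs(log(res$icr_cnc_crude$point)) <
                3 * res$icr_cnc_crude$log_se)
  # empirical ratio within the odds-spread bounds up to Monte-Carlo noise
  se <- sqrt(res$icr_co_crude$log_se^2 + res$icr_co_stratified$log_se^2)
  expect_lt(log(res$cir_empirical), log(res$bounds["upper"]) + 3 * se)
  expect_gt(log(res$cir_empirical), log(res$bounds["lower"]) - 3 * se)
  # homogeneous strata: no bias, no odds spread
  hom <- sim_params(n = c(30000, 30000), p_s = 0.3, p_e = 0.3, se_or = 1,
                    beta0 = -3, beta3 = 0, seed = 64)
  res2 <- cir_empirical(simulate_population(hom))
  expect_true(abs(log(res2$cir_empirical)) <
                3 * sqrt(res2$icr_co_crude$log_se^2 +
                         res2$icr_co_stratified$log_se^2))
  expect_lt(res2$upsilon_s, 1.1)
  expect_error(cir_empirical(simulate_population(sim_params(n = 1000,
                                                            seed = 65))),
               "stratum")
})

test_that("design variances and efficiency ratios", {
  v <- variance_comparison(uniform_table(10))
  expect_equal(v$var_full, 0.8)
  expect_equal(v$var_cc, 0.8)
  expect_equal(v$var_co, 0.4)
  v2 <- variance_comparison(ref_table())
  expect_equal(v2$var_full,
               1/10 + 1/190 + 1/20 + 1/180 + 1/30 + 1/170 + 1/120 + 1/80)
  expect_equal(v2$var_co, 1/10 + 1/20 + 1/30 + 1/120)
  set.seed(66)
  for (i in 1:20) {
    v3 <- variance_comparison(random_table(), p = runif(1, 0.05, 1))
    expect_lt(v3$ratio_co_full, 1)
    expect_lt(v3$ratio_co_cc, 1)
  }
  expect_error(variance_comparison(
    two_by_four_table(0, 1, 1, 1, 1, 1, 1, 1)), "positive")
})
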