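#' Implied S-E association among controls (rare-disease sensitivity)
#'
#' Given the baseline disease risk `p0 = P(D | S-E-)`, the three relative
#' risks against the S-E- reference and the S-E association in the full
#' sample, returns the S-E association implied among controls:
#'
#' `seor_control = seor_cnc * ((1/p0 - 1)(1/p0 - rr_se)) /
#'                 ((1/p0 - rr_s)(1/p0 - rr_e))`
#'
#' As `p0 -> 0` the factor tends to 1, so the control-population
#' association converges to the full-sample association — the quantitative
#' content of the rare-disease assumption. The symbol sometimes written
#' RR_G in the gene-environment literature is the susceptibility-factor
#' relative risk `rr_s` here.
#'
#' Both `seor_cnc` and the returned value are in the *conventional*
#' odds-ratio orientation (concordant over discordant S-E cells): the
#' multiplicative factor above is specific to that orientation. To relate
#' the result to the correction-factor orientation of [seor_cnc()] and
#' [seor_control()], take reciprocals on both sides. On an expected table
#' from [expected_table()] with `se_or = 1`, the conventional control odds
#' ratio `BH/(DF)` reproduces this formula exactly.
#'
#' @param p0 baseline risk `P(D | S-E-)` in (0, 1).
#' @param rr_s,rr_e,rr_se relative risks vs the S-E- reference; each must
#'   be strictly less than `1/p0`.
#' @param seor_cnc S-E association factor in the full sample (default 1).
#' @return The implied control-population S-E association (numeric).
#' @export
#' @examples
#' seor_control_sensitivity(0.2, 1, 1, 3)  # 0.5
seor_control_sensitivity <- function(p0, rr_s, rr_e, rr_se, seor_cnc = 1) {
  stopifnot(is.numeric(p0), p0 > 0, p0 < 1,
            rr_s > 0, rr_e > 0, rr_se > 0, seor_cnc > 0)
  inv <- 1 / p0
  if (inv <= rr_s || inv <= rr_e || inv <= rr_se)
    stop("domain error: 1/p0 must exceed each relative risk ",
         "(a stratum risk would reach or exceed 1)", call. = FALSE)
  seor_cnc * ((inv - 1) * (inv - rr_se)) / ((inv - rr_s) * (inv - rr_e))
}

#' Sensitivity grid for the rare-disease approximation
#'
#' Evaluates [seor_control_sensitivity()] over a grid of baseline risks and
#' susceptibility relative risks, reproducing the usual sensitivity surface
#' for how far the control-population S-E association drifts from the
#' full-sample value as the disease becomes common. Default grids span
#' baseline risks 0.1-6% and `rr_s` 1-4, the range over which the
#' approximation visibly degrades.
#'
#' @param p0 vector of baseline risks.
#' @param rr_s vector of susceptibility relative risks.
#' @param rr_e,rr_se scalars held fixed across the grid.
#' @param seor_cnc full-sample S-E association factor.
#' @return A data frame with columns `p0`, `rr_s`, `seor_control`.
#' @export
sensitivity_grid <- function(p0 = c(0.001, 0.005, 0.01, 0.03, 0.06),
                             rr_s = c(1, 1.5, 2.5, 4),
                             rr_e = 1, rr_se = 1, seor_cnc = 1) {
  g <- expand.grid(p0 = p0, rr_s = rr_s)
  g$seor_control <- mapply(function(p, r)
    seor_control_sensitivity(p, r, rr_e, rr_se, seor_cnc), g$p0, g$rr_s)
  g
}

#' Confounding interaction ratio
#'
#' The confounding interaction ratio quantifies how much a crude
#' (unstratified) full-sample ICR is biased away from the
#' stratification-adjusted ICR by subpopulation dependence:
#' `CIR = r_se * cv_s * cv_e + 1`, where `r_se` is the correlation between
#' the stratum-level susceptibility prevalence odds and exposure prevalence
#' odds, and `cv_s`, `cv_e` are their coefficients of variation. CIR = 1
#' (no bias) whenever the odds are uncorrelated or either shows no
#' variation across strata.
#'
#' @param r_se correlation in `[-1, 1]`.
#' @param cv_s,cv_e non-negative coefficients of variation.
#' @return The CIR (numeric).
#' @export
#' @examples
#' cir(0.5, 0.4, 0.3)  # 1.06
cir <- function(r_se, cv_s, cv_e) {
  stopifnot(is.numeric(r_se), abs(r_se) <= 1,
            is.numeric(cv_s), cv_s >= 0, is.numeric(cv_e), cv_e >= 0)
  r_se * cv_s * cv_e + 1
}

#' Bounds on the confounding interaction ratio
#'
#' Upper and lower bounds for the CIR from the spread of the stratum-level
#' prevalence odds: with `u_s >= 1` the ratio of the largest to the
#' smallest susceptibility frequency odds across strata and `u_e >= 1` the
#' analogue for exposure,
#'
#' `U = sqrt(u_s u_e) (sqrt(u_s u_e) + 1)^2 /
#'      ((sqrt(u_s u_e) + u_s)(sqrt(u_s u_e) + u_e))`, `L = 1/U`.
#'
#' `U >= 1` always, `U * L = 1` exactly, and `U = L = 1` whenever either
#' odds shows no variation (`u_s = 1` or `u_e = 1`).
#'
#' @param upsilon_s,upsilon_e odds spread ratios, both `>= 1`.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' cir_bounds(4, 4)  # lower 0.64, upper 1.5625
cir_bounds <- function(upsilon_s, upsilon_e) {
  if (!is.numeric(upsilon_s) || !is.numeric(upsilon_e) ||
      upsilon_s < 1 || upsilon_e < 1)
    stop("both odds spread ratios must be >= 1", call. = FALSE)
  r <- sqrt(upsilon_s * upsilon_e)
  u <- r * (r + 1)^2 / ((r + upsilon_s) * (r + upsilon_e))
  c(lower = 1 / u, upper = u)
}

# size-weighted helpers for stratum summaries
wmean <- function(x, w) sum(w * x) / sum(w)
wsd <- function(x, w) sqrt(wmean((x - wmean(x, w))^2, w))
wcor <- function(x, y, w) {
  cx <- x - wmean(x, w); cy <- y - wmean(y, w)
  wmean(cx * cy, w) / (wsd(x, w) * wsd(y, w))
}

#' Empirical confounding interaction ratio
#'
#' Measures the stratification bias of the case-only route on
#' subject-level data with a `stratum` column. Hidden subpopulations with
#' correlated susceptibility and exposure prevalences induce an S-E
#' association in the pooled population even when S and E are independent
#' within every stratum; the pooled case-only estimate absorbs that
#' association while the stratum-adjusted one does not. The empirical CIR
#' is therefore the ratio of the crude (pooled) case-only interaction
#' estimate to the stratum-adjusted case-only estimate (stratum indicator
#' terms in the logistic fit). Note that the *full-sample* interaction fit
#' `D ~ S*E` is untouched by this mechanism when the disease model is
#' shared across strata — stratification that shifts only the S and E
#' margins biases the case-only route, not the cases-plus-non-cases route;
#' both pairs of fits are returned so this can be seen directly.
#'
#' Alongside the empirical ratio, the stratum-level ingredients of the
#' analytic approximation [cir()] are computed from the per-stratum
#' prevalence odds: the correlation `r_se`, the coefficients of variation
#' `cv_s`, `cv_e`, and the max/min spread ratios `upsilon_s`, `upsilon_e`
#' that feed [cir_bounds()]. Stratum summaries are weighted by stratum
#' size by default (`weighted = FALSE` for unweighted variants). The
#' analytic CIR is a first-order approximation: expect close agreement
#' for modest odds variation (CVs up to roughly 0.3) and growing
#' divergence beyond.
#'
#' @param data subject-level data in the layout of [as_subject_data()],
#'   with binary S and E and a `stratum` column.
#' @param level confidence level for the interaction fits.
#' @param weighted weight stratum summaries by stratum size?
#' @return A list with `icr_co_crude`, `icr_co_stratified`,
#'   `icr_cnc_crude`, `icr_cnc_stratified` (all [effect_estimate()]),
#'   `cir_empirical` (= crude / stratified case-only point),
#'   `cir_predicted` (from [cir()]), `r_se`, `cv_s`, `cv_e`, `upsilon_s`,
#'   `upsilon_e`, `bounds` and the per-stratum odds table.
#' @export
cir_empirical <- function(data, level = 0.95, weighted = TRUE) {
  if (is.null(data$stratum))
    stop("data must carry a 'stratum' column", call. = FALSE)
  if (!is_binary01(data$S) || !is_binary01(data$E))
    stop("stratum prevalence odds require binary S and E", call. = FALSE)
  strata <- split(data, data$stratum)
  if (length(strata) < 2L)
    stop("at least 2 strata are required", call. = FALSE)
  tab <- do.call(rbind, lapply(names(strata), function(k) {
    d <- strata[[k]]
    ps <- mean(d$S); pe <- mean(d$E)
    if (ps %in% c(0, 1) || pe %in% c(0, 1))
      stop(sprintf("stratum '%s': degenerate S or E prevalence", k),
           call. = FALSE)
    data.frame(stratum = k, n = nrow(d),
               odds_s = ps / (1 - ps), odds_e = pe / (1 - pe))
  }))
  w <- if (weighted) tab$n else rep(1, nrow(tab))
  cv_s <- wsd(tab$odds_s, w) / wmean(tab$odds_s, w)
  cv_e <- wsd(tab$odds_e, w) / wmean(tab$odds_e, w)
  # with no odds variation the correlation is undefined and irrelevant;
  # clamp to [-1, 1] against floating-point overshoot (exact for 2 strata)
  r_se <- if (cv_s == 0 || cv_e == 0) 0
          else max(-1, min(1, wcor(tab$odds_s, tab$odds_e, w)))
  u_s <- max(tab$odds_s) / min(tab$odds_s)
  u_e <- max(tab$odds_e) / min(tab$odds_e)

  dat2 <- data
  dat2$stratum <- factor(dat2$stratum)
  cases <- dat2[dat2$D == 1, , drop = FALSE]
  if (nrow(cases) < 8L)
    stop("too few cases for the case-only CIR fits", call. = FALSE)
  safe_fit <- function(formula, d, term, nm) {
    fit <- tryCatch(fit_logit(formula, d), error = function(e)
      stop(sprintf("%s fit failed: %s", nm, conditionMessage(e)),
           call. = FALSE))
    wald_estimate(fit, term, level, nm)
  }
  co_crude <- safe_fit(S ~ E, cases, "E", "ICR_co (crude)")
  co_strat <- safe_fit(S ~ E + stratum, cases, "E", "ICR_co (stratified)")
  cnc_crude <- fit_interaction(data, covariates = character(), level = level)
  cnc_strat <- safe_fit(D ~ S * E + stratum, dat2, "S:E",
                        "ICR_c/nc (stratified)")

  list(icr_co_crude = co_crude, icr_co_stratified = co_strat,
       icr_cnc_crude = cnc_crude, icr_cnc_stratified = cnc_strat,
       cir_empirical = co_crude$point / co_strat$point,
       cir_predicted = cir(r_se, cv_s, cv_e),
       r_se = r_se, cv_s = cv_s, cv_e = cv_e,
       upsilon_s = u_s, upsilon_e = u_e,
       bounds = cir_bounds(u_s, u_e), strata = tab)
}

#' Asymptotic variance comparison across designs
#'
#' Asymptotic variances of the log interaction estimate in the three
#' designs, from the reciprocal-cell formulas: full sample
#' (`sum(1/cell)` over all eight cells), case-control at control sampling
#' fraction `p` (cases plus `p x non-cases` controls) and case-only
#' (`1/a + 1/c + 1/e + 1/g`). The case-only variance is a strict subset of
#' the positive terms of the other two, so its efficiency ratios are
#' always below 1 — the efficiency gain bought by the independence
#' assumption.
#'
#' @param t a [two_by_four_table()] with positive cells.
#' @param p control sampling fraction for the case-control column.
#' @return A list with `var_full`, `var_cc`, `var_co` and the ratios
#'   `ratio_co_full = var_co/var_full`, `ratio_co_cc = var_co/var_cc`.
#' @export
#' @examples
#' variance_comparison(two_by_four_table(10, 10, 10, 10, 10, 10, 10, 10))
variance_comparison <- function(t, p = 1) {
  stopifnot(inherits(t, "two_by_four"))
  if (p <= 0 || p > 1)
    stop("control sampling fraction p must lie in (0, 1]", call. = FALSE)
  ca <- cells(t, c("a", "c", "e", "g"))
  nc <- cells(t, c("B", "D", "F", "H"))
  if (any(ca == 0) || any(nc == 0))
    stop("all eight cells must be positive", call. = FALSE)
  var_full <- sum(1 / ca) + sum(1 / nc)
  var_cc <- sum(1 / ca) + sum(1 / (p * nc))
  var_co <- sum(1 / ca)
  list(var_full = var_full, var_cc = var_cc, var_co = var_co,
       ratio_co_full = var_co / var_full, ratio_co_cc = var_co / var_cc)
}
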