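#' Aggregated 2x4 interaction table (cases and non-cases)
#'
#' The eight counts of a study with cases and non-cases cross-classified by
#' a binary susceptibility factor S and a binary environmental exposure E.
#' The four strata are, in order, S-E-, S+E-, S-E+ and S+E+; `a`, `c`, `e`,
#' `g` are the case counts in those strata and `B`, `D`, `F`, `H` the
#' non-case counts. Counts may be real-valued (expected tables produced by
#' [expected_table()] are), but must be non-negative with positive total.
#'
#' @param a,c,e,g case counts for the S-E-, S+E-, S-E+ and S+E+ strata.
#' @param B,D,F non-case counts for S-E-, S+E- and S-E+.
#' @param H non-case count for S+E+.
#' @return An object of class `two_by_four` (named list of the eight counts).
#' @seealso [rr_effects()], [or_effects()], [icr_cnc()], [seor_cnc()],
#'   [sample_case_control()], [variance_comparison()]
#' @export
#' @examples
#' t <- two_by_four_table(a = 10, B = 190, c = 20, D = 180,
#'                        e = 30, F = 170, g = 120, H = 80)
#' icr_cnc(t, scale = "multiplicative", basis = "RR")
two_by_four_table <- function(a, B, c, D, e, F, g, H) {
  x <- vapply(list(a = a, B = B, c = c, D = D, e = e, F = F, g = g, H = H),
              function(v) as.numeric(v)[1L], numeric(1))
  if (any(!is.finite(x)) || any(x < 0))
    stop("invalid table: all eight counts must be finite and non-negative",
         call. = FALSE)
  if (sum(x) <= 0)
    stop("invalid table: total count must be positive", call. = FALSE)
  structure(as.list(x), class = "two_by_four")
}

#' Case-only counts
#'
#' The four case counts of a case-only study: `a` (S-E-), `c` (S+E-),
#' `e` (S-E+) and `g` (S+E+).
#'
#' @param a,c,e,g case counts by S x E stratum.
#' @return An object of class `case_only_counts`.
#' @export
case_only_counts <- function(a, c, e, g) {
  x <- vapply(list(a = a, c = c, e = e, g = g),
              function(v) as.numeric(v)[1L], numeric(1))
  if (any(!is.finite(x)) || any(x < 0))
    stop("invalid case-only counts: must be finite and non-negative",
         call. = FALSE)
  structure(as.list(x), class = "case_only_counts")
}

#' Case-control table
#'
#' Case counts `a`, `c`, `e`, `g` plus sampled control counts `b`, `d`,
#' `f`, `h` for the same four S x E strata, optionally carrying the control
#' sampling fraction `p` as metadata.
#'
#' @param a,c,e,g case counts (S-E-, S+E-, S-E+, S+E+).
#' @param b,d,f,h control counts for the same strata.
#' @param p control sampling fraction in (0, 1], or `NA` if unknown.
#' @return An object of class `case_control_table`.
#' @export
case_control_table <- function(a, c, e, g, b, d, f, h, p = NA_real_) {
  x <- vapply(list(a = a, c = c, e = e, g = g, b = b, d = d, f = f, h = h),
              function(v) as.numeric(v)[1L], numeric(1))
  if (any(!is.finite(x)) || any(x < 0))
    stop("invalid case-control table: counts must be finite and non-negative",
         call. = FALSE)
  if (!is.na(p) && (p <= 0 || p > 1))
    stop("control sampling fraction p must lie in (0, 1]", call. = FALSE)
  structure(c(as.list(x), list(p = p)), class = "case_control_table")
}

#' @export
print.two_by_four <- function(x, ...) {
  m <- matrix(unlist(x[c("a", "c", "e", "g", "B", "D", "F", "H")]),
              nrow = 4, dimnames = list(
                c("S-E-", "S+E-", "S-E+", "S+E+"), c("cases", "non-cases")))
  cat("2x4 interaction table (cases and non-cases)\n")
  print(m)
  invisible(x)
}

#' @export
print.case_only_counts <- function(x, ...) {
  cat("case-only counts: a(S-E-) =", x$a, " c(S+E-) =", x$c,
      " e(S-E+) =", x$e, " g(S+E+) =", x$g, "\n")
  invisible(x)
}

#' @export
print.case_control_table <- function(x, ...) {
  m <- matrix(unlist(x[c("a", "c", "e", "g", "b", "d", "f", "h")]),
              nrow = 4, dimnames = list(
                c("S-E-", "S+E-", "S-E+", "S+E+"), c("cases", "controls")))
  cat("case-control table",
      if (!is.na(x$p)) sprintf("(control sampling fraction p = %g)", x$p),
      "\n")
  print(m)
  invisible(x)
}

cells <- function(t, nm) unlist(t[nm], use.names = TRUE)

# optional Haldane-Anscombe continuity correction on a cell vector
apply_cc <- function(x, correct) if (correct) x + 0.5 else x

#' Relative risks from a 2x4 table
#'
#' Relative risks for susceptibility alone (`RR_s`), exposure alone
#' (`RR_e`) and the joint stratum (`RR_se`), each against the S-E-
#' reference row: `RR_s = c(a+B) / (a(c+D))` and analogues. Intervals are
#' log-Wald with the usual relative-risk variance
#' `1/c - 1/(c+D) + 1/a - 1/(a+B)` (and analogues).
#'
#' @param t a [two_by_four_table()].
#' @param level confidence level.
#' @param correct apply a Haldane-Anscombe +0.5 continuity correction to all
#'   cells before estimation (flagged in the output). Off by default.
#' @return A list of three [effect_estimate()] objects named `RR_s`, `RR_e`,
#'   `RR_se`. A zero numerator cell gives a flagged zero point estimate
#'   without an interval unless `correct = TRUE`.
#' @export
rr_effects <- function(t, level = 0.95, correct = FALSE) {
  stopifnot(inherits(t, "two_by_four"))
  x <- apply_cc(cells(t, c("a", "B", "c", "D", "e", "F", "g", "H")), correct)
  tot <- c(x["a"] + x["B"], x["c"] + x["D"], x["e"] + x["F"], x["g"] + x["H"])
  if (any(tot == 0))
    stop("invalid table: every S x E row total must be positive", call. = FALSE)
  if (x["a"] == 0)
    stop("degenerate reference: no cases in the S-E- reference stratum",
         call. = FALSE)
  fl <- if (correct) "continuity" else character()
  one <- function(num, den_tot, nm) {
    if (num == 0)
      return(effect_estimate(0, NA_real_, level, "log-Wald", nm,
                             flags = c(fl, "zero-numerator")))
    pt <- (num * tot[1]) / (x["a"] * den_tot)
    se <- sqrt(1 / num - 1 / den_tot + 1 / x["a"] - 1 / tot[1])
    effect_estimate(unname(pt), unname(se), level, "log-Wald", nm, flags = fl)
  }
  list(RR_s = one(x["c"], tot[2], "RR_s"),
       RR_e = one(x["e"], tot[3], "RR_e"),
       RR_se = one(x["g"], tot[4], "RR_se"))
}

#' Odds ratios from a 2x4 table
#'
#' Odds ratios against the S-E- reference row: `OR_s = cB/(aD)`,
#' `OR_e = eB/(aF)`, `OR_se = gB/(aH)`, with log-Wald intervals whose
#' variance is the sum of reciprocal cells of the 2x2 involved.
#'
#' @inheritParams rr_effects
#' @return A list of three [effect_estimate()] objects named `OR_s`, `OR_e`,
#'   `OR_se`.
#' @export
or_effects <- function(t, level = 0.95, correct = FALSE) {
  stopifnot(inherits(t, "two_by_four"))
  x <- apply_cc(cells(t, c("a", "B", "c", "D", "e", "F", "g", "H")), correct)
  fl <- if (correct) "continuity" else character()
  one <- function(case, noncase, nm) {
    used <- c(x["a"], x["B"], case, noncase)
    if (any(used == 0))
      stop(sprintf("zero cell in the 2x2 for %s; consider correct = TRUE", nm),
           call. = FALSE)
    pt <- (case * x["B"]) / (x["a"] * noncase)
    se <- sqrt(sum(1 / used))
    effect_estimate(unname(pt), unname(se), level, "log-Wald", nm, flags = fl)
  }
  list(OR_s = one(x["c"], x["D"], "OR_s"),
       OR_e = one(x["e"], x["F"], "OR_e"),
       OR_se = one(x["g"], x["H"], "OR_se"))
}

#' Case-only interaction contrast ratio
#'
#' The case-only ICR `ag/(ce)`: the S-E odds ratio among cases, which under
#' S-E independence in the full population equals the multiplicative
#' interaction contrast ratio of the full cases-plus-non-cases design.
#' The log-scale variance is `1/a + 1/c + 1/e + 1/g`, the asymptotic
#' variance of the case-only logistic interaction estimator.
#'
#' @param k a [case_only_counts()] object.
#' @inheritParams rr_effects
#' @return An [effect_estimate()] with estimand `"ICR_co"`.
#' @export
#' @examples
#' icr_co(case_only_counts(a = 10, c = 20, e = 30, g = 120)) # 2.0
icr_co <- function(k, level = 0.95, correct = FALSE) {
  stopifnot(inherits(k, "case_only_counts"))
  x <- apply_cc(cells(k, c("a", "c", "e", "g")), correct)
  fl <- if (correct) "continuity" else character()
  if (x["c"] == 0 || x["e"] == 0) {
    bad <- paste(names(x[c("c", "e")])[x[c("c", "e")] == 0], collapse = ", ")
    stop(sprintf("zero denominator cell (%s) in case-only ICR; consider correct = TRUE",
                 bad), call. = FALSE)
  }
  if (x["a"] == 0 || x["g"] == 0)
    return(effect_estimate(0, NA_real_, level, "log-Wald", "ICR_co",
                           flags = c(fl, "zero-numerator")))
  pt <- (x["a"] * x["g"]) / (x["c"] * x["e"])
  se <- sqrt(sum(1 / x))
  effect_estimate(unname(pt), unname(se), level, "log-Wald", "ICR_co",
                  flags = fl)
}

#' S-E association factor in the full sample
#'
#' The quantity `((c+D)(e+F)) / ((a+B)(g+H))` computed from the S x E
#' margins of the full sample (cases plus non-cases). This is the exact
#' factor linking the case-only ICR to the full-sample ICR
#' (`ICR_c/nc = ICR_co x seor_cnc`); it equals 1 exactly when S and E are
#' independent in the full sample, and is the *reciprocal* of the
#' conventionally oriented S-E odds ratio (stored in the output as
#' `conventional_or`). The independence decision is the same in either
#' orientation. Interval: log-Wald with variance equal to the sum of
#' reciprocal S x E margins.
#'
#' @inheritParams rr_effects
#' @return An [effect_estimate()] with estimand `"S-E OR_c/nc"` and extra
#'   field `conventional_or`.
#' @export
seor_cnc <- function(t, level = 0.95, correct = FALSE) {
  stopifnot(inherits(t, "two_by_four"))
  x <- apply_cc(cells(t, c("a", "B", "c", "D", "e", "F", "g", "H")), correct)
  m <- c(x["a"] + x["B"], x["c"] + x["D"], x["e"] + x["F"], x["g"] + x["H"])
  if (any(m == 0))
    stop("invalid table: every S x E margin must be positive", call. = FALSE)
  pt <- (m[2] * m[3]) / (m[1] * m[4])
  se <- sqrt(sum(1 / m))
  effect_estimate(unname(pt), unname(se), level, "log-Wald", "S-E OR_c/nc",
                  flags = if (correct) "continuity" else character(),
                  extra = list(conventional_or = unname(1 / pt)))
}

#' Full-sample interaction contrast ratio
#'
#' Interaction contrast ratio in a study with cases and non-cases, on the
#' multiplicative scale (`RR_se/(RR_s RR_e)` or `OR_se/(OR_s OR_e)`) or the
#' additive scale (the relative excess risk due to interaction,
#' `RR_se - (RR_s + RR_e - 1)`, likewise on the OR basis). The
#' multiplicative RR-basis estimate satisfies the exact identity
#' `icr_cnc = icr_co x seor_cnc`.
#'
#' No closed-form interval is offered for the multiplicative table-based
#' estimate: its components share cells, so the naive delta-method variance
#' is wrong. Use `ci = "bootstrap"` (multinomial resampling of the eight
#' cells, seeded) or fit the saturated logistic model via
#' [fit_interaction()] on expanded data. The additive RERI may be negative
#' and is reported without an interval.
#'
#' @inheritParams rr_effects
#' @param scale `"multiplicative"` or `"additive"` (RERI).
#' @param basis `"RR"` or `"OR"`: which single-effect measures enter.
#' @param ci `"none"` (default) or `"bootstrap"` for the multiplicative
#'   scale.
#' @param boot_reps number of bootstrap resamples.
#' @param seed seed for the bootstrap resampling.
#' @return An [effect_estimate()].
#' @export
icr_cnc <- function(t, scale = c("multiplicative", "additive"),
                    basis = c("RR", "OR"), level = 0.95, correct = FALSE,
                    ci = c("none", "bootstrap"), boot_reps = 2000,
                    seed = NULL) {
  stopifnot(inherits(t, "two_by_four"))
  scale <- match.arg(scale)
  basis <- match.arg(basis)
  ci <- match.arg(ci)
  singles <- if (basis == "RR") rr_effects(t, level, correct)
             else or_effects(t, level, correct)
  pts <- vapply(singles, `[[`, numeric(1), "point")
  estimand <- sprintf("ICR_c/nc (%s, %s basis)", scale, basis)
  fl <- if (correct) "continuity" else character()
  if (scale == "additive") {
    pt <- pts[3] - (pts[1] + pts[2] - 1)
    out <- list(estimand = estimand, point = unname(pt), log_se = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, level = level,
                method = "point only (RERI)", flags = fl)
    class(out) <- "effect_estimate"
    return(out)
  }
  if (any(pts[1:2] == 0))
    stop("zero single-effect estimate: multiplicative ICR undefined",
         call. = FALSE)
  pt <- pts[3] / (pts[1] * pts[2])
  if (ci == "none")
    return(effect_estimate(unname(pt), NA_real_, level,
                           "point only (no closed-form CI)", estimand,
                           flags = fl))
  x <- cells(t, c("a", "B", "c", "D", "e", "F", "g", "H"))
  n <- sum(x)
  bp <- with_seed(seed, {
    draws <- stats::rmultinom(boot_reps, round(n), x / n)
    apply(draws, 2, function(cl) {
      cl <- cl + 0.5 * (any(cl == 0))  # continuity only when needed
      tt <- two_by_four_table(cl[1], cl[2], cl[3], cl[4],
                              cl[5], cl[6], cl[7], cl[8])
      s <- if (basis == "RR") rr_effects(tt) else or_effects(tt)
      p <- vapply(s, `[[`, numeric(1), "point")
      p[3] / (p[1] * p[2])
    })
  })
  qs <- stats::quantile(bp, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  effect_estimate(unname(pt), stats::sd(log(bp)), level,
                  sprintf("multinomial bootstrap (%d resamples)", boot_reps),
                  estimand, ci_low = qs[1], ci_high = qs[2], flags = fl)
}

#' Sample controls from a full table
#'
#' Generates a case-control table from a cases-plus-non-cases table by
#' selecting a fraction `p` of the non-cases in each stratum as controls.
#' `mode = "expected"` takes the expected counts `p x non-cases` (rounded
#' half away from zero, with a warning when rounding occurs);
#' `mode = "binomial"` draws each control count from Binomial(non-cases, p)
#' with the given seed.
#'
#' @inheritParams rr_effects
#' @param p control sampling fraction in (0, 1].
#' @param mode `"expected"` or `"binomial"`.
#' @param seed seed used for `mode = "binomial"`.
#' @return A [case_control_table()].
#' @export
sample_case_control <- function(t, p, mode = c("expected", "binomial"),
                                seed = NULL) {
  stopifnot(inherits(t, "two_by_four"))
  mode <- match.arg(mode)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("control sampling fraction p must lie in (0, 1]", call. = FALSE)
  nc <- cells(t, c("B", "D", "F", "H"))
  ctr <- if (mode == "expected") {
    ex <- p * nc
    r <- floor(ex + 0.5)  # half away from zero (counts are non-negative)
    if (any(abs(r - ex) > 1e-9))
      warning("expected control counts p x non-cases are non-integer; rounded half away from zero")
    r
  } else {
    with_seed(seed, stats::rbinom(4L, size = as.integer(round(nc)), prob = p))
  }
  ctr <- unname(ctr)
  case_control_table(a = t$a, c = t$c, e = t$e, g = t$g,
                     b = ctr[1], d = ctr[2], f = ctr[3], h = ctr[4], p = p)
}

#' Case-control interaction contrast ratio
#'
#' `ICR_cc = OR_se/(OR_s OR_e) = (ag/ce)(df/bh)`, with log-Wald interval
#' from the asymptotic variance `sum(1/cell)` over all eight cells. Under
#' expected-value control sampling the sampling fraction cancels, so
#' `ICR_cc` equals the OR-basis full-sample ICR of the source table.
#'
#' @param cc a [case_control_table()].
#' @inheritParams rr_effects
#' @return An [effect_estimate()] with estimand `"ICR_cc"`.
#' @export
icr_cc <- function(cc, level = 0.95, correct = FALSE) {
  stopifnot(inherits(cc, "case_control_table"))
  x <- apply_cc(cells(cc, c("a", "c", "e", "g", "b", "d", "f", "h")), correct)
  if (any(x == 0))
    stop(sprintf("zero cell (%s) in case-control ICR; consider correct = TRUE",
                 paste(names(x)[x == 0], collapse = ", ")), call. = FALSE)
  pt <- (x["a"] * x["g"]) / (x["c"] * x["e"]) *
        (x["d"] * x["f"]) / (x["b"] * x["h"])
  se <- sqrt(sum(1 / x))
  effect_estimate(unname(pt), unname(se), level, "log-Wald", "ICR_cc",
                  flags = if (correct) "continuity" else character())
}

#' S-E association factor among controls
#'
#' The control-population analogue of [seor_cnc()]: `df/(bh)` (equivalently
#' `DF/(BH)` in the source population). Equals 1 exactly when S and E are
#' independent among controls, the condition under which `ICR_cc = ICR_co`.
#' As with [seor_cnc()] this is the correction-factor orientation; the
#' conventional odds ratio is its reciprocal (returned as
#' `conventional_or`).
#'
#' @inheritParams icr_cc
#' @return An [effect_estimate()] with estimand `"S-E OR_control"`.
#' @export
seor_control <- function(cc, level = 0.95, correct = FALSE) {
  stopifnot(inherits(cc, "case_control_table"))
  x <- apply_cc(cells(cc, c("b", "d", "f", "h")), correct)
  if (any(x == 0))
    stop(sprintf("zero control cell (%s); consider correct = TRUE",
                 paste(names(x)[x == 0], collapse = ", ")), call. = FALSE)
  pt <- (x["d"] * x["f"]) / (x["b"] * x["h"])
  se <- sqrt(sum(1 / x))
  effect_estimate(unname(pt), unname(se), level, "log-Wald", "S-E OR_control",
                  flags = if (correct) "continuity" else character(),
                  extra = list(conventional_or = unname(1 / pt)))
}

#' Correct a case-only ICR for S-E dependence
#'
#' Multiplies a case-only ICR by the full-sample S-E association factor,
#' recovering the full-sample ICR via the exact identity
#' `ICR_c/nc = ICR_co x seor_cnc`. Two interval constructions are offered:
#' `"bound_product"` multiplies the interval limits pairwise
#' (lower x lower, upper x upper), matching the printed arithmetic this
#' correction is traditionally reported with; `"lognormal_sum"` adds the
#' two log-scale standard errors in quadrature, which is the conventional
#' lognormal approximation but ignores the covariance between the two
#' estimates (they share the case data).
#'
#' @param icr_co an [effect_estimate()] for the case-only ICR.
#' @param seor an [effect_estimate()] for the S-E association factor
#'   (from [seor_cnc()] or [fit_independence()]).
#' @param ci_method `"bound_product"` (default) or `"lognormal_sum"`.
#' @param level confidence level for `"lognormal_sum"`; the bound-product
#'   interval inherits the level of the inputs.
#' @return An [effect_estimate()] with estimand `"ICR_c/nc (adjusted)"`.
#' @export
#' @examples
#' co <- effect_estimate(1.14, ci_low = 1.03, ci_high = 1.37, estimand = "ICR_co")
#' se <- effect_estimate(1.06, ci_low = 1.03, ci_high = 1.10)
#' adjust_icr(co, se)  # 1.21 (1.06-1.51) after rounding to 2 decimals
adjust_icr <- function(icr_co, seor,
                       ci_method = c("bound_product", "lognormal_sum"),
                       level = 0.95) {
  stopifnot(inherits(icr_co, "effect_estimate"),
            inherits(seor, "effect_estimate"))
  ci_method <- match.arg(ci_method)
  if (icr_co$point <= 0 || seor$point <= 0)
    stop("both point estimates must be positive", call. = FALSE)
  pt <- icr_co$point * seor$point
  if (ci_method == "bound_product") {
    effect_estimate(pt, NA_real_, icr_co$level, "bound product",
                    "ICR_c/nc (adjusted)",
                    ci_low = icr_co$ci_low * seor$ci_low,
                    ci_high = icr_co$ci_high * seor$ci_high)
  } else {
    se1 <- if (is.finite(icr_co$log_se)) icr_co$log_se
           else log_se_from_ci(icr_co$ci_low, icr_co$ci_high, icr_co$level)
    se2 <- if (is.finite(seor$log_se)) seor$log_se
           else log_se_from_ci(seor$ci_low, seor$ci_high, seor$level)
    effect_estimate(pt, sqrt(se1^2 + se2^2), level,
                    "lognormal quadrature (covariance ignored)",
                    "ICR_c/nc (adjusted)")
  }
}

#' Case-only ICR implied by a full-sample ICR
#'
#' Solves the identity `ICR_c/nc = ICR_co x seor_cnc` for the case-only
#' ICR: given the full-sample ICR and the S-E association, returns the
#' case-only ICR the identity implies. `seor` may be supplied in either
#' orientation via `orientation`: the correction factor of [seor_cnc()]
#' (default) or the conventionally oriented S-E odds ratio (its
#' reciprocal).
#'
#' @param icr_cnc full-sample ICR (number or [effect_estimate()]).
#' @param seor S-E association in the full sample (number or
#'   [effect_estimate()]).
#' @param orientation `"factor"` for the correction-factor orientation of
#'   [seor_cnc()], `"conventional"` for the ordinary S-E odds ratio.
#' @return An [effect_estimate()] (point only) with estimand `"ICR_co"`.
#' @export
#' @examples
#' implied_case_only(2.5, 1)                              # 2.5
#' implied_case_only(1.0, 2.0, orientation = "conventional")  # 2.0
implied_case_only <- function(icr_cnc, seor,
                              orientation = c("factor", "conventional")) {
  orientation <- match.arg(orientation)
  p1 <- if (inherits(icr_cnc, "effect_estimate")) icr_cnc$point else icr_cnc
  p2 <- if (inherits(seor, "effect_estimate")) seor$point else seor
  stopifnot(is.numeric(p1), is.numeric(p2), p1 > 0, p2 > 0)
  if (orientation == "conventional") p2 <- 1 / p2
  effect_estimate(p1 / p2, NA_real_, method = "identity (point only)",
                  estimand = "ICR_co")
}
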