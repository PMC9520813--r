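#' Decide whether S and E are independent
#'
#' Applies the independence rule to an estimated S-E association. The
#' default `"ci_contains_one"` rule declares independence when the
#' confidence interval contains 1 (this reproduces the usual practice of
#' reading the Wald interval of the S-E fit). The `"tolerance"` rule
#' additionally requires the point estimate itself to be close to 1:
#' `|log(point)| <= log(1 + epsilon)`. Both rules are invariant to the
#' orientation (factor vs conventional) of the association estimate.
#'
#' @param seor an [effect_estimate()] with a confidence interval.
#' @param rule `"ci_contains_one"` or `"tolerance"`.
#' @param epsilon tolerance for the `"tolerance"` rule (must be > 0).
#' @return A list with elements `decision` (`"independent"` or
#'   `"dependent"`), `rule` and `rationale`.
#' @export
#' @examples
#' independence_decision(effect_estimate(0.76, ci_low = 0.47, ci_high = 1.06))
independence_decision <- function(seor,
                                  rule = c("ci_contains_one", "tolerance"),
                                  epsilon = NULL) {
  stopifnot(inherits(seor, "effect_estimate"))
  rule <- match.arg(rule)
  if (is.na(seor$ci_low) || is.na(seor$ci_high))
    stop("the S-E association estimate has no confidence interval",
         call. = FALSE)
  in_ci <- seor$ci_low <= 1 && 1 <= seor$ci_high
  if (rule == "ci_contains_one") {
    dec <- if (in_ci) "independent" else "dependent"
    why <- sprintf(
      "%g%% CI (%.4g-%.4g) %s 1", 100 * seor$level, seor$ci_low,
      seor$ci_high, if (in_ci) "contains" else "excludes")
  } else {
    if (is.null(epsilon) || !is.numeric(epsilon) || epsilon <= 0)
      stop("the tolerance rule requires epsilon > 0", call. = FALSE)
    close <- abs(log(seor$point)) <= log(1 + epsilon)
    dec <- if (in_ci && close) "independent" else "dependent"
    why <- sprintf(
      "%g%% CI %s 1; |log point| = %.4g %s log(1 + %.3g)",
      100 * seor$level, if (in_ci) "contains" else "excludes",
      abs(log(seor$point)), if (close) "<=" else ">", epsilon)
  }
  list(decision = dec, rule = rule, rationale = why)
}

#' Case-only interaction analysis
#'
#' Runs the five-step case-only procedure for a susceptibility factor S
#' and an environmental exposure E on a binary disease D:
#'
#' 1. odds ratio for a one-unit difference in E alone;
#' 2. odds ratio for a one-unit difference in S alone;
#' 3. the multiplicative interaction contrast ratio `exp(b3)` from the
#'    full-sample logistic fit `logit P(D=1) = b0 + b1 S + b2 E + b3 SE`;
#' 4. the S-E independence check in the full sample (cases and non-cases);
#' 5. the case-only ICR from cases alone — used as the headline estimate
#'    when S and E are judged independent, and otherwise corrected by the
#'    S-E association factor (`ICR_co x seor`). The corrected estimate is
#'    always computed and stored, whatever the decision, so borderline
#'    decisions can be inspected.
#'
#' The model is specified as `D ~ S * E` (optionally `D ~ S * E + C1 + C2`
#' for covariate adjustment): the two variables of the interaction term are
#' taken as susceptibility and exposure — by convention the first is the
#' susceptibility factor; override with `susceptibility` / `exposure` if
#' the formula order differs. Remaining main-effect terms are covariates,
#' entered in the interaction, independence and case-only fits.
#'
#' @param formula model formula `D ~ S * E (+ covariates)`.
#' @param data a data frame containing the variables.
#' @param susceptibility,exposure optional variable names overriding the
#'   role assignment read from the formula.
#' @param level confidence level for all intervals.
#' @param independence_rule passed to [independence_decision()].
#' @param epsilon tolerance for the `"tolerance"` rule.
#' @param ci_method interval construction for the corrected estimate,
#'   passed to [adjust_icr()].
#' @param continuous_s behaviour for non-binary S, passed to
#'   [fit_independence()] and [fit_case_only()].
#' @return An object of class `caseonly`: a list with the five estimates
#'   (`or_e`, `or_s`, `icr_cnc`, `seor_cnc`, `icr_co`, `icr_adjusted`),
#'   the `decision`, the name of the `headline` estimate, a `narrative`
#'   of estimate/explanation rows, sample counts and the call. Methods:
#'   `print`, `summary`, `coef`, `confint`, `plot`.
#' @seealso [write_report()] to serialize the result; [simulate_population()]
#'   to generate synthetic input.
#' @export
#' @examples
#' pop <- simulate_population(sim_params(n = 4000, beta3 = log(2), seed = 7))
#' fit <- caseonly(D ~ S * E, data = pop)
#' summary(fit)
caseonly <- function(formula, data, susceptibility = NULL, exposure = NULL,
                     level = 0.95,
                     independence_rule = c("ci_contains_one", "tolerance"),
                     epsilon = NULL,
                     ci_method = c("bound_product", "lognormal_sum"),
                     continuous_s = c("error", "approximate")) {
  independence_rule <- match.arg(independence_rule)
  ci_method <- match.arg(ci_method)
  continuous_s <- match.arg(continuous_s)
  cl <- match.call()

  tm <- stats::terms(formula)
  labs <- attr(tm, "term.labels")
  inter <- labs[grepl(":", labs, fixed = TRUE)]
  if (length(inter) != 1L)
    stop("the formula must contain exactly one interaction term, e.g. D ~ S * E",
         call. = FALSE)
  pair <- strsplit(inter, ":", fixed = TRUE)[[1L]]
  s_var <- if (is.null(susceptibility)) pair[1L] else susceptibility
  e_var <- if (is.null(exposure)) pair[2L] else exposure
  d_var <- as.character(formula[[2L]])
  covs <- setdiff(labs, c(inter, s_var, e_var))

  sd <- as_subject_data(data, d = d_var, s = s_var, e = e_var,
                        covariates = covs)
  log_entries <- list(
    runlog("data", sprintf(
      "n = %d used (%d dropped listwise); S = %s, E = %s, D = %s%s",
      nrow(sd), attr(sd, "n_dropped"), s_var, e_var, d_var,
      if (length(covs)) paste0("; covariates: ", paste(covs, collapse = ", "))
      else "")))

  step <- function(what, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("step '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE))
    log_entries[[length(log_entries) + 1L]] <<- runlog(what, format(res))
    res
  }

  or_e <- step("single-effect E", fit_single_effect(sd, "E", level))
  or_s <- step("single-effect S", fit_single_effect(sd, "S", level))
  cnc <- step("full-sample interaction", fit_interaction(sd, covs, level))
  seor <- step("independence check",
               fit_independence(sd, covs, level, continuous_s))
  dec <- independence_decision(seor, independence_rule, epsilon)
  log_entries[[length(log_entries) + 1L]] <-
    runlog("decision", paste(dec$decision, "-", dec$rationale))
  cases <- sd[sd$D == 1, , drop = FALSE]
  attr(cases, "covariates") <- covs
  co <- step("case-only interaction",
             fit_case_only(cases, covs, level, continuous_s))
  adj <- adjust_icr(co, seor, ci_method, level)
  headline <- if (dec$decision == "independent") "icr_co" else "icr_adjusted"

  narrative <- list(
    c(estimate = format(or_e),
      explanation = sprintf(
        "Per one-unit difference in %s the odds of %s differ %s-fold.",
        e_var, d_var, format(round(or_e$point, 2)))),
    c(estimate = format(or_s),
      explanation = sprintf(
        "Per one-unit difference in %s the odds of %s differ %s-fold.",
        s_var, d_var, format(round(or_s$point, 2)))),
    c(estimate = format(cnc),
      explanation = sprintf(
        "Full-sample multiplicative ICR exp(b3) = %s.",
        format(round(cnc$point, 2)))),
    c(estimate = format(seor),
      explanation = sprintf(
        "S-E association factor in the full sample; %s -> %s.",
        dec$rationale, dec$decision)),
    c(estimate = format(co),
      explanation = if (dec$decision == "independent")
        "S and E judged independent: the case-only ICR stands in for the full-sample ICR."
      else
        "S and E judged dependent: the case-only ICR must be corrected by the S-E factor."),
    c(estimate = format(adj),
      explanation = sprintf(
        "Case-only ICR x S-E factor = corrected full-sample ICR (%s).",
        if (headline == "icr_adjusted") "headline" else
          "stored for sensitivity only")))

  structure(list(
    or_e = or_e, or_s = or_s, icr_cnc = cnc, seor_cnc = seor,
    icr_co = co, icr_adjusted = adj,
    decision = dec, headline = headline, narrative = narrative,
    n_used = nrow(sd), n_cases = nrow(cases),
    variables = list(d = d_var, s = s_var, e = e_var, covariates = covs),
    config = list(level = level, independence_rule = independence_rule,
                  epsilon = epsilon, ci_method = ci_method,
                  continuous_s = continuous_s),
    log = log_entries, call = cl), class = "caseonly")
}

runlog <- function(step, detail) {
  e <- list(step = step, detail = detail)
  attr(e, "time") <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  e
}

caseonly_estimates <- function(x) {
  list(or_e = x$or_e, or_s = x$or_s, icr_cnc = x$icr_cnc,
       seor_cnc = x$seor_cnc, icr_co = x$icr_co,
       icr_adjusted = x$icr_adjusted)
}

#' @export
print.caseonly <- function(x, ...) {
  cat("Case-only interaction analysis\n")
  cat(sprintf("  n = %d (%d cases); S = %s, E = %s\n", x$n_used, x$n_cases,
              x$variables$s, x$variables$e))
  cat(sprintf("  independence: %s (%s)\n", x$decision$decision,
              x$decision$rationale))
  hl <- x[[x$headline]]
  cat(sprintf("  headline %s: %s\n", hl$estimand, format(hl)))
  invisible(x)
}

#' @export
summary.caseonly <- function(object, ...) {
  structure(list(fit = object), class = "summary.caseonly")
}

#' @export
print.summary.caseonly <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nStep-by-step estimates:\n")
  w <- max(nchar(vapply(f$narrative, `[[`, "", "estimate")))
  for (row in f$narrative)
    cat(sprintf("  %-*s  %s\n", w, row[["estimate"]], row[["explanation"]]))
  invisible(x)
}

#' @export
coef.caseonly <- function(object, ...) {
  vapply(caseonly_estimates(object), `[[`, numeric(1), "point")
}

#' @export
confint.caseonly <- function(object, parm, level, ...) {
  est <- caseonly_estimates(object)
  if (!missing(parm)) est <- est[parm]
  out <- t(vapply(est, function(e) c(e$ci_low, e$ci_high), numeric(2)))
  colnames(out) <- c("lower", "upper")
  out
}

#' Forest-style display of a case-only analysis
#'
#' Plots the five workflow estimates with their confidence intervals on a
#' log axis, marking the null value 1 and the headline estimate.
#'
#' @param x a `caseonly` fit.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.caseonly <- function(x, ...) {
  est <- rev(caseonly_estimates(x))
  pts <- vapply(est, `[[`, numeric(1), "point")
  lo <- vapply(est, `[[`, numeric(1), "ci_low")
  hi <- vapply(est, `[[`, numeric(1), "ci_high")
  labs <- vapply(est, `[[`, "", "estimand")
  k <- length(pts)
  rng <- range(c(pts, lo, hi, 1), na.rm = TRUE)
  graphics::plot(pts, seq_len(k), log = "x", xlim = rng, yaxt = "n",
                 xlab = "ratio estimate (log scale)", ylab = "",
                 pch = 19, ...)
  graphics::axis(2, at = seq_len(k), labels = labs, las = 1, cex.axis = 0.8)
  graphics::segments(lo, seq_len(k), hi, seq_len(k))
  graphics::abline(v = 1, lty = 2, col = "grey40")
  hl <- which(rev(names(caseonly_estimates(x))) == x$headline)
  graphics::points(pts[hl], hl, pch = 19, col = "red3")
  invisible(x)
}
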