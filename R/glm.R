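#' Standardize subject-level data
#'
#' Maps arbitrary column names onto the standard layout used by all fitting
#' functions: `D` (binary disease indicator), `S` (susceptibility factor,
#' binary 0/1 or continuous), `E` (exposure, binary 0/1 or continuous),
#' optional covariate columns (kept under their own names) and an optional
#' `stratum` column. Rows with missing values in any used column are
#' dropped listwise and counted.
#'
#' @param data a data frame.
#' @param d,s,e names of the disease, susceptibility and exposure columns.
#' @param covariates character vector of covariate column names.
#' @param stratum optional name of a stratum label column.
#' @return A data frame with columns `D`, `S`, `E`, the covariates and
#'   (if requested) `stratum`; attributes `covariates` (names) and
#'   `n_dropped` (rows removed by listwise deletion).
#' @export
as_subject_data <- function(data, d = "D", s = "S", e = "E",
                            covariates = character(), stratum = NULL) {
  used <- c(d, s, e, covariates, stratum)
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(D = data[[d]], S = data[[s]], E = data[[e]])
  for (cv in covariates) out[[cv]] <- data[[cv]]
  if (!is.null(stratum)) out$stratum <- data[[stratum]]
  keep <- stats::complete.cases(out)
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no complete rows remain", call. = FALSE)
  if (!all(out$D %in% c(0, 1)))
    stop("disease indicator must be coded 0/1", call. = FALSE)
  if (length(unique(out$S)) < 2L || length(unique(out$E)) < 2L)
    stop("S and E must each take at least 2 distinct values", call. = FALSE)
  attr(out, "covariates") <- covariates
  attr(out, "n_dropped") <- dropped
  out
}

is_binary01 <- function(x) all(x %in% c(0, 1))

# shared glm runner: tight convergence so saturated fits reproduce
# closed-form table estimators to numerical identity
fit_logit <- function(formula, data) {
  stats::glm(formula, data = data, family = stats::binomial(),
             control = stats::glm.control(epsilon = 1e-12, maxit = 200))
}

check_separation <- function(fit, flags) {
  if (any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    warning("possible separation: a fitted log-scale coefficient exceeds 15; ",
            "consider a continuity-corrected table analysis", call. = FALSE)
    flags <- c(flags, "separation")
  }
  if (!fit$converged) flags <- c(flags, "non-convergence")
  flags
}

wald_estimate <- function(fit, term, level, estimand, flags = character(),
                          negate = FALSE, extra = list()) {
  cf <- stats::coef(fit)
  if (!(term %in% names(cf)) || is.na(cf[term]))
    stop(sprintf("fit failed: coefficient '%s' not estimable (collinearity?)",
                 term), call. = FALSE)
  flags <- check_separation(fit, flags)
  b <- unname(cf[term])
  se <- sqrt(stats::vcov(fit)[term, term])
  if (negate) b <- -b
  extra <- c(extra, list(coefficients = cf, n_used = stats::nobs(fit),
                         converged = fit$converged))
  effect_estimate(exp(b), unname(se), level, "Wald (logistic fit)", estimand,
                  flags = flags, extra = extra)
}

#' Single-effect odds ratio from a logistic fit
#'
#' Maximum-likelihood logistic regression of disease on one predictor
#' (susceptibility or exposure alone); returns the odds ratio per one-unit
#' difference with a Wald interval. On data expanded from a count table
#' with binary predictors this reproduces the crude 2x2 odds ratio exactly.
#'
#' @param data subject-level data in the layout of [as_subject_data()].
#' @param which `"S"` or `"E"`: which predictor to fit.
#' @param level confidence level.
#' @return An [effect_estimate()].
#' @export
fit_single_effect <- function(data, which = c("E", "S"), level = 0.95) {
  which <- match.arg(which)
  if (!is_binary01(data$D) || length(unique(data$D)) < 2L)
    stop("disease indicator must be binary with both classes present",
         call. = FALSE)
  fit <- fit_logit(stats::reformulate(which, response = "D"), data)
  wald_estimate(fit, which, level,
                sprintf("OR_%s (per 1-unit %s)", tolower(which), which))
}

#' Full-sample interaction from a logistic fit
#'
#' Fits `logit P(D = 1) = b0 + b1 S + b2 E + b3 SE (+ covariates)` and
#' returns `exp(b3)`, the multiplicative interaction contrast ratio. The
#' identical model serves cohort-type (cases plus non-cases) and
#' case-control samples; only the interpretation (`ICR_c/nc` vs `ICR_cc`)
#' differs.
#'
#' @inheritParams fit_single_effect
#' @param covariates covariate column names entered as main effects;
#'   defaults to the `covariates` attribute of `data`.
#' @return An [effect_estimate()] with estimand `"ICR_c/nc"`.
#' @export
fit_interaction <- function(data, covariates = attr(data, "covariates"),
                            level = 0.95) {
  if (!is_binary01(data$D) || length(unique(data$D)) < 2L)
    stop("disease indicator must be binary with both classes present",
         call. = FALSE)
  if (stats::var(data$S * data$E) == 0)
    stop("the S x E product term has no variation", call. = FALSE)
  rhs <- c("S * E", covariates)
  fit <- fit_logit(stats::reformulate(rhs, response = "D"), data)
  wald_estimate(fit, "S:E", level, "ICR_c/nc")
}

#' S-E independence check from a regression fit
#'
#' Estimates the S-E association factor in the full sample (cases plus
#' non-cases). For binary S this is a logistic fit of S on E
#' (`logit P(S = 1) = eta0 + eta1 E`), reported in the correction-factor
#' orientation `exp(-eta1)` so that it matches [seor_cnc()] on collapsed
#' tables and so that multiplying the case-only ICR by it recovers the
#' full-sample ICR; the conventionally oriented odds ratio `exp(eta1)` is
#' carried in the output as `conventional_or`. The factor equals 1 exactly
#' under independence and the independence decision is orientation-
#' invariant.
#'
#' For continuous S no logistic formulation exists; with
#' `continuous_s = "approximate"` the factor is estimated as
#' `exp(-slope)` from a least-squares regression of S on E, flagged
#' `"continuous-S approximation"` — a pragmatic screen, not an odds ratio.
#'
#' @inheritParams fit_interaction
#' @param continuous_s `"error"` (default) or `"approximate"`: behaviour
#'   when S is not binary 0/1.
#' @return An [effect_estimate()] with estimand `"S-E OR_c/nc"` and extra
#'   field `conventional_or`.
#' @export
fit_independence <- function(data, covariates = attr(data, "covariates"),
                             level = 0.95,
                             continuous_s = c("error", "approximate")) {
  continuous_s <- match.arg(continuous_s)
  rhs <- c("E", covariates)
  if (is_binary01(data$S)) {
    fit <- fit_logit(stats::reformulate(rhs, response = "S"), data)
    est <- wald_estimate(fit, "E", level, "S-E OR_c/nc", negate = TRUE)
    est$conventional_or <- 1 / est$point
    return(est)
  }
  if (continuous_s == "error")
    stop("S is not binary 0/1; the logistic independence model is undefined. ",
         "Use continuous_s = \"approximate\" for a least-squares screen.",
         call. = FALSE)
  fit <- stats::lm(stats::reformulate(rhs, response = "S"), data = data)
  b <- -unname(stats::coef(fit)["E"])
  se <- sqrt(stats::vcov(fit)["E", "E"])
  effect_estimate(exp(b), unname(se), level,
                  "Wald (least-squares S on E)", "S-E OR_c/nc",
                  flags = "continuous-S approximation",
                  extra = list(conventional_or = exp(-b),
                               n_used = stats::nobs(fit), converged = TRUE))
}

#' Case-only interaction from a regression fit
#'
#' Fits `logit P(S = 1) = g0 + g1 E (+ covariates)` among cases only and
#' returns `exp(g1)`, the case-only ICR; with covariates supplied this is
#' the covariate-adjusted case-only estimate. The input must contain cases
#' only (`D == 1` for every row) — passing non-cases is a contract
#' violation, not a filtering request.
#'
#' For continuous S, `continuous_s = "approximate"` reports `exp(slope)`
#' from a least-squares regression of S on E among cases, flagged
#' `"continuous-S approximation"`: the binary-S logistic path is the
#' supported default and the approximation is a documented pragmatic
#' extension, not an estimator defined by the case-only theory.
#'
#' @inheritParams fit_independence
#' @return An [effect_estimate()] with estimand `"ICR_co"`.
#' @export
fit_case_only <- function(data, covariates = attr(data, "covariates"),
                          level = 0.95,
                          continuous_s = c("error", "approximate")) {
  continuous_s <- match.arg(continuous_s)
  if (any(data$D != 1))
    stop("contract violation: fit_case_only() requires cases only (all D == 1); ",
         "subset the data explicitly before calling", call. = FALSE)
  rhs <- c("E", covariates)
  if (is_binary01(data$S)) {
    if (length(unique(data$S)) < 2L)
      stop("S is constant among cases: case-only fit impossible", call. = FALSE)
    fit <- fit_logit(stats::reformulate(rhs, response = "S"), data)
    return(wald_estimate(fit, "E", level, "ICR_co"))
  }
  if (continuous_s == "error")
    stop("S is not binary 0/1; the case-only logistic model is undefined. ",
         "Use continuous_s = \"approximate\" for a least-squares estimate.",
         call. = FALSE)
  fit <- stats::lm(stats::reformulate(rhs, response = "S"), data = data)
  b <- unname(stats::coef(fit)["E"])
  se <- sqrt(stats::vcov(fit)["E", "E"])
  effect_estimate(exp(b), unname(se), level,
                  "Wald (least-squares S on E, cases)", "ICR_co",
                  flags = "continuous-S approximation",
                  extra = list(n_used = stats::nobs(fit), converged = TRUE))
}

#' Expand a count table to subject-level rows
#'
#' Turns a [two_by_four_table()] (or [case_only_counts()]) into one row per
#' subject with columns `D`, `S`, `E`, so the regression estimators can be
#' checked against their closed-form table counterparts. Counts are rounded
#' to integers.
#'
#' @param t a `two_by_four` or `case_only_counts` object.
#' @return A subject-level data frame in the standard layout.
#' @export
table_to_subjects <- function(t) {
  grid <- data.frame(S = c(0, 1, 0, 1), E = c(0, 0, 1, 1))
  if (inherits(t, "two_by_four")) {
    n_case <- round(unlist(t[c("a", "c", "e", "g")]))
    n_non <- round(unlist(t[c("B", "D", "F", "H")]))
  } else if (inherits(t, "case_only_counts")) {
    n_case <- round(unlist(t[c("a", "c", "e", "g")]))
    n_non <- rep(0L, 4L)
  } else stop("unsupported table type", call. = FALSE)
  idx <- rep(seq_len(4L), times = n_case + n_non)
  out <- grid[idx, , drop = FALSE]
  out$D <- unlist(mapply(function(nc, nn) c(rep(1L, nc), rep(0L, nn)),
                         n_case, n_non, SIMPLIFY = FALSE))
  rownames(out) <- NULL
  out <- out[, c("D", "S", "E")]
  attr(out, "covariates") <- character()
  out
}
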