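#' Ratio effect estimates
#'
#' Container for a ratio-scale effect estimate (relative risk, odds ratio or
#' interaction contrast ratio) together with its log-scale standard error and
#' a two-sided confidence interval. All estimators in the package return
#' objects of this class.
#'
#' @param point point estimate on the ratio scale (must be > 0 unless a
#'   zero-numerator flag is set).
#' @param log_se standard error of `log(point)`; `NA` when no closed-form
#'   variance is offered.
#' @param level two-sided confidence level in (0, 1).
#' @param method label describing how the interval was constructed.
#' @param estimand short label for the quantity estimated, e.g. `"ICR_co"`.
#' @param ci_low,ci_high explicit interval limits; when omitted and `log_se`
#'   is finite, log-Wald limits `exp(log(point) +/- z * log_se)` are used.
#' @param flags character vector of quality flags (e.g. `"continuity"`,
#'   `"zero-numerator"`, `"separation"`, `"continuous-S approximation"`).
#' @param extra named list of additional fields carried along (sample sizes,
#'   companion quantities); stored verbatim.
#'
#' @return An object of class `effect_estimate`: a list with elements
#'   `estimand`, `point`, `log_se`, `ci_low`, `ci_high`, `level`, `method`
#'   and `flags`.
#' @export
effect_estimate <- function(point, log_se = NA_real_, level = 0.95,
                            method = "log-Wald", estimand = "",
                            ci_low = NULL, ci_high = NULL,
                            flags = character(), extra = list()) {
  stopifnot(is.numeric(point), length(point) == 1L)
  if (!is.na(point) && point < 0)
    stop("ratio point estimate must be non-negative", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("confidence level must lie in (0, 1)", call. = FALSE)
  if (is.null(ci_low) || is.null(ci_high)) {
    if (is.finite(log_se) && !is.na(point) && point > 0) {
      z <- stats::qnorm(1 - (1 - level) / 2)
      ci_low <- exp(log(point) - z * log_se)
      ci_high <- exp(log(point) + z * log_se)
    } else {
      ci_low <- NA_real_
      ci_high <- NA_real_
    }
  }
  out <- list(estimand = estimand, point = point, log_se = log_se,
              ci_low = ci_low, ci_high = ci_high, level = level,
              method = method, flags = flags)
  out[names(extra)] <- extra
  class(out) <- "effect_estimate"
  out
}

#' @export
print.effect_estimate <- function(x, digits = 4, ...) {
  lab <- if (nzchar(x$estimand)) x$estimand else "estimate"
  ci <- if (is.na(x$ci_low)) "CI not available" else
    sprintf("%g%% CI %s-%s", 100 * x$level,
            format(x$ci_low, digits = digits),
            format(x$ci_high, digits = digits))
  cat(sprintf("%s: %s (%s) [%s]\n", lab,
              format(x$point, digits = digits), ci, x$method))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.effect_estimate <- function(x, digits = 2, ...) {
  if (is.na(x$ci_low))
    format(round(x$point, digits), nsmall = digits)
  else
    sprintf("%s (%g%% CI %s-%s)",
            format(round(x$point, digits), nsmall = digits), 100 * x$level,
            format(round(x$ci_low, digits), nsmall = digits),
            format(round(x$ci_high, digits), nsmall = digits))
}

# log-scale SE recovered from a symmetric-on-log-scale Wald interval
log_se_from_ci <- function(ci_low, ci_high, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  (log(ci_high) - log(ci_low)) / (2 * z)
}

# run expr with a temporary RNG state seeded by `seed` (NULL = use current)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
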