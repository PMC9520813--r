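#' Joint S x E cell probabilities with given margins and odds ratio
#'
#' The unique 2x2 joint distribution of binary S and E with marginal
#' prevalences `p_s`, `p_e` and S-E odds ratio `se_or` (conventional
#' orientation: concordant over discordant cells). The S+E+ probability is
#' the admissible root of the Plackett quadratic; the remaining cells
#' follow from the margins.
#'
#' @param p_s,p_e marginal prevalences in (0, 1).
#' @param se_or S-E odds ratio, > 0.
#' @return Named probability vector `c("S-E-", "S+E-", "S-E+", "S+E+")`,
#'   summing to 1.
#' @export
#' @examples
#' joint_probs(0.5, 0.5, 9)  # S+E+ cell 0.375
joint_probs <- function(p_s, p_e, se_or) {
  stopifnot(p_s > 0, p_s < 1, p_e > 0, p_e < 1, se_or > 0)
  if (se_or == 1) {
    p11 <- p_s * p_e
  } else {
    aa <- se_or - 1
    bb <- 1 + (p_s + p_e) * aa
    p11 <- (bb - sqrt(bb^2 - 4 * se_or * aa * p_s * p_e)) / (2 * aa)
  }
  p <- c("S-E-" = 1 - p_s - p_e + p11, "S+E-" = p_s - p11,
         "S-E+" = p_e - p11, "S+E+" = p11)
  if (any(p < -1e-12))
    stop("no admissible joint distribution for these inputs", call. = FALSE)
  pmax(p, 0)
}

#' Simulation parameters
#'
#' Parameters of the synthetic population: per-stratum sample size,
#' marginal prevalences of a binary susceptibility factor S and binary
#' exposure E, the within-stratum S-E odds ratio, and the logistic disease
#' model `logit P(D=1) = beta0 + beta1 S + beta2 E + beta3 SE`. Supplying
#' vectors for `n`, `p_s`, `p_e` or `se_or` creates that many strata
#' (values recycled), labelled in a `stratum` column. An optional
#' confounder path draws `C ~ N(0, 1)` first and generates S and E
#' conditionally independent given C, with log-odds slopes `alpha_s` and
#' `alpha_e` — this induces a marginal S-E association operating through C.
#'
#' Defaults describe a moderately sized exposure study: 20,000 subjects,
#' 30% prevalence of both factors, S-E independence, a rare disease
#' (baseline risk `plogis(-5)`, about 0.7%), single effects of 1.5 on the
#' odds scale and no interaction.
#'
#' @param n subjects per stratum.
#' @param p_s,p_e prevalences per stratum, in (0, 1).
#' @param se_or within-stratum S-E odds ratio (conventional orientation).
#' @param beta0,beta1,beta2,beta3 logistic disease-model coefficients.
#' @param confounder optional `list(alpha_s =, alpha_e =)` confounder spec;
#'   requires `se_or = 1` (the S-E association then comes from C alone).
#' @param seed integer seed; every draw in [simulate_population()] flows
#'   from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n = 20000, p_s = 0.3, p_e = 0.3, se_or = 1,
                       beta0 = -5, beta1 = log(1.5), beta2 = log(1.5),
                       beta3 = 0, confounder = NULL, seed = 20220929) {
  k <- max(length(n), length(p_s), length(p_e), length(se_or))
  p <- list(n = rep_len(n, k), p_s = rep_len(p_s, k),
            p_e = rep_len(p_e, k), se_or = rep_len(se_or, k),
            beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
            confounder = confounder, seed = seed, n_strata = k)
  stopifnot(all(p$n >= 1), all(p$p_s > 0 & p$p_s < 1),
            all(p$p_e > 0 & p$p_e < 1), all(p$se_or > 0))
  if (!is.null(confounder)) {
    stopifnot(is.list(confounder),
              all(c("alpha_s", "alpha_e") %in% names(confounder)))
    if (any(p$se_or != 1))
      stop("with a confounder spec, set se_or = 1: the S-E association is ",
           "induced by C", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "sim_params: %d stratum/strata, n = %s, p_s = %s, p_e = %s, se_or = %s\n",
    x$n_strata, paste(x$n, collapse = "/"), paste(x$p_s, collapse = "/"),
    paste(x$p_e, collapse = "/"), paste(x$se_or, collapse = "/")))
  cat(sprintf("  disease model: logit = %.3g + %.3g S + %.3g E + %.3g SE\n",
              x$beta0, x$beta1, x$beta2, x$beta3))
  if (!is.null(x$confounder))
    cat(sprintf("  confounder: alpha_s = %.3g, alpha_e = %.3g\n",
                x$confounder$alpha_s, x$confounder$alpha_e))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Simulate a synthetic population
#'
#' Draws a subject-level population from a [sim_params()] specification:
#' within each stratum, (S, E) from the joint distribution of
#' [joint_probs()] (or via the confounder path), then D from the logistic
#' disease model. Identical parameters (including the seed) give an
#' identical population.
#'
#' @param params a [sim_params()] object.
#' @return A subject-level data frame with columns `D`, `S`, `E`, plus `C`
#'   (confounder path) and `stratum` (multi-stratum specs); carries the
#'   `covariates` attribute used by the fitting functions.
#' @export
#' @examples
#' head(simulate_population(sim_params(n = 100, seed = 1)))
simulate_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    strata <- lapply(seq_len(params$n_strata), function(k) {
      n <- params$n[k]
      if (is.null(params$confounder)) {
        pr <- joint_probs(params$p_s[k], params$p_e[k], params$se_or[k])
        cell <- sample.int(4L, n, replace = TRUE, prob = pr)
        d <- data.frame(S = c(0, 1, 0, 1)[cell], E = c(0, 0, 1, 1)[cell])
      } else {
        C <- stats::rnorm(n)
        d <- data.frame(
          S = stats::rbinom(n, 1L, stats::plogis(
            stats::qlogis(params$p_s[k]) + params$confounder$alpha_s * C)),
          E = stats::rbinom(n, 1L, stats::plogis(
            stats::qlogis(params$p_e[k]) + params$confounder$alpha_e * C)),
          C = C)
      }
      d$stratum <- k
      d
    })
    out <- do.call(rbind, strata)
    lp <- params$beta0 + params$beta1 * out$S + params$beta2 * out$E +
      params$beta3 * out$S * out$E
    out$D <- stats::rbinom(nrow(out), 1L, stats::plogis(lp))
    if (params$n_strata == 1L) out$stratum <- NULL
    covs <- if (!is.null(params$confounder)) "C" else character()
    out <- out[, c("D", "S", "E", covs,
                   if (params$n_strata > 1L) "stratum")]
    attr(out, "covariates") <- covs
    out
  })
}

#' Expected 2x4 table under the simulation model
#'
#' Closed-form expected counts `n P(S, E) P(D | S, E)` (and complements)
#' under a [sim_params()] specification, summed over strata. On expected
#' tables the closed-form estimators hit their analytic targets exactly —
#' e.g. the OR-basis full-sample ICR equals `exp(beta3)` — making them
#' exact oracles for identity tests. Not defined for the confounder path
#' (the S-E law is then a mixture over C with no closed 2x2 form).
#'
#' @param params a [sim_params()] object without a confounder spec.
#' @return A real-valued [two_by_four_table()].
#' @export
expected_table <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$confounder))
    stop("expected_table() is not available for the confounder path",
         call. = FALSE)
  tot_case <- tot_non <- numeric(4L)
  s_ind <- c(0, 1, 0, 1); e_ind <- c(0, 0, 1, 1)
  for (k in seq_len(params$n_strata)) {
    pr <- joint_probs(params$p_s[k], params$p_e[k], params$se_or[k])
    risk <- stats::plogis(params$beta0 + params$beta1 * s_ind +
                          params$beta2 * e_ind + params$beta3 * s_ind * e_ind)
    tot_case <- tot_case + params$n[k] * pr * risk
    tot_non <- tot_non + params$n[k] * pr * (1 - risk)
  }
  two_by_four_table(a = tot_case[1], B = tot_non[1], c = tot_case[2],
                    D = tot_non[2], e = tot_case[3], F = tot_non[3],
                    g = tot_case[4], H = tot_non[4])
}

# collapse simulated binary data to the eight counts
subjects_to_table <- function(data) {
  if (!is_binary01(data$S) || !is_binary01(data$E))
    stop("collapsing to a 2x4 table requires binary S and E", call. = FALSE)
  idx <- 1L + data$S + 2L * data$E
  ca <- tabulate(idx[data$D == 1], nbins = 4L)
  no <- tabulate(idx[data$D == 0], nbins = 4L)
  two_by_four_table(a = ca[1], B = no[1], c = ca[2], D = no[2],
                    e = ca[3], F = no[3], g = ca[4], H = no[4])
}

#' Monte-Carlo recovery experiment
#'
#' Repeatedly simulates populations, estimates the interaction by the
#' case-only, full-sample and corrected estimators, and summarizes bias,
#' spread and Wald coverage per estimator. Because ratio estimates are
#' compared multiplicatively, bias and Monte-Carlo standard errors are
#' reported on the log scale (with the geometric mean alongside the
#' arithmetic mean). For binary S and E the estimators are the closed-form
#' table statistics, which coincide with the saturated logistic
#' maximum-likelihood fits; Wald intervals use the reciprocal-cell
#' asymptotic variances of [variance_comparison()].
#'
#' @param params a [sim_params()] object; replicate `r` uses seed
#'   `seed + r`.
#' @param n_reps number of replicates (>= 2).
#' @param seed base seed for the replicate stream.
#' @param level confidence level for coverage.
#' @return An object of class `recovery_experiment`: a list with `summary`
#'   (one row per estimator: geometric mean, arithmetic mean, log-scale
#'   bias and MC standard error, mean Wald SE, coverage of the true
#'   `exp(beta3)`), `truth`, `n_reps`, `n_failed`, and
#'   `efficiency_ok` (empirical Var of the log case-only estimate below
#'   that of the log full-sample estimate).
#' @export
recovery_experiment <- function(params, n_reps = 200, seed = 1,
                                level = 0.95) {
  stopifnot(inherits(params, "sim_params"), n_reps >= 2)
  truth <- exp(params$beta3)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- vector("list", n_reps)
  failed <- 0L
  for (r in seq_len(n_reps)) {
    p <- params
    p$seed <- seed + r
    t <- subjects_to_table(simulate_population(p))
    x <- unlist(t)
    if (any(x[c("a", "c", "e", "g")] == 0)) { failed <- failed + 1L; next }
    v <- variance_comparison(t)
    co <- (t$a * t$g) / (t$c * t$e)
    full <- or_effects(t)
    cnc <- full$OR_se$point / (full$OR_s$point * full$OR_e$point)
    seor <- seor_cnc(t)$point
    rows[[r]] <- data.frame(
      icr_co = co, icr_cnc = cnc, icr_adjusted = co * seor,
      se_co = sqrt(v$var_co), se_cnc = sqrt(v$var_full))
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) < 2L)
    stop("too few successful replicates", call. = FALSE)
  summarize <- function(est, wald_se = NULL) {
    lg <- log(res[[est]])
    out <- data.frame(
      estimator = est, geo_mean = exp(mean(lg)), mean = mean(res[[est]]),
      log_bias = mean(lg) - log(truth),
      mc_se_log = stats::sd(lg) / sqrt(nrow(res)),
      emp_var_log = stats::var(lg),
      mean_wald_se = if (is.null(wald_se)) NA_real_ else mean(res[[wald_se]]),
      coverage = if (is.null(wald_se)) NA_real_ else
        mean(abs(lg - log(truth)) <= z * res[[wald_se]]))
    out
  }
  summary <- rbind(summarize("icr_co", "se_co"),
                   summarize("icr_cnc", "se_cnc"),
                   summarize("icr_adjusted"))
  structure(list(
    summary = summary, truth = truth, n_reps = n_reps, n_failed = failed,
    efficiency_ok = summary$emp_var_log[summary$estimator == "icr_co"] <
      summary$emp_var_log[summary$estimator == "icr_cnc"],
    level = level, params = params, seed = seed, replicates = res),
    class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Monte-Carlo recovery experiment: %d replicates (%d failed), truth = %g\n",
    x$n_reps, x$n_failed, x$truth))
  print(format(x$summary, digits = digits), row.names = FALSE)
  cat(if (x$efficiency_ok)
    "case-only estimator empirically more precise than full-sample estimator\n"
    else
    "WARNING: case-only estimator NOT more precise in this run\n")
  invisible(x)
}
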