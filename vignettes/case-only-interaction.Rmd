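---
title: "Case-only estimation of susceptibility-exposure interaction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only estimation of susceptibility-exposure interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caseonly)
```

## The problem

Epidemiologists often ask whether a host characteristic that modifies
disease risk — a genotype, a biomarker level such as glycohemoglobin, or
simply age — interacts with an environmental exposure: is the joint effect
of carrying the susceptibility factor S *and* sustaining the exposure E
larger (or smaller) than the product of their separate effects on a binary
disease D? On the multiplicative scale this departure is the interaction
contrast ratio (ICR). The conventional route estimates it from a cohort or
case-control sample via the logistic model

$$\operatorname{logit} P(D=1) = \beta_0 + \beta_1 S + \beta_2 E + \beta_3 SE,
\qquad \mathrm{ICR} = e^{\beta_3}.$$

The case-only design discards the non-cases entirely. Among cases, the
association between S and E itself carries the interaction: fitting
$\operatorname{logit} P(S=1) = \gamma_0 + \gamma_1 E$ on cases alone gives
$e^{\gamma_1}$, which equals the full-sample multiplicative ICR whenever S
and E are independent in the population the cases came from. The prize is
precision: the asymptotic variance of $\hat\gamma_1$ is
$1/a + 1/c + 1/e + 1/g$ (the four case counts by S×E stratum), a strict
subset of the positive terms in the variance of $\hat\beta_3$, which adds
the four non-case reciprocals. The price is the independence assumption,
and everything in this package revolves around stating, checking, and —
when it fails — correcting for it.

## Notation and the exact identities

All closed-form work happens on the 2×4 table of counts: cases
$a, c, e, g$ and non-cases $B, D, F, H$ for the strata S−E−, S+E−, S−E+ and
S+E+. Three ICRs exist, one per design:

* case-only: $\mathrm{ICR}_{co} = ag/(ce)$, the S-E odds ratio among cases;
* full sample (cases and non-cases): on the risk-ratio basis
  $\mathrm{ICR}_{c/nc} = \mathrm{RR}_{se}/(\mathrm{RR}_s \mathrm{RR}_e)$,
  on the odds-ratio basis the analogous ratio of ORs;
* case-control at control sampling fraction $p$:
  $\mathrm{ICR}_{cc} = \mathrm{OR}_{se}/(\mathrm{OR}_s \mathrm{OR}_e)$.

Two exact factorizations tie these together, and neither needs a
rare-disease argument:

$$\mathrm{ICR}_{c/nc} = \mathrm{ICR}_{co} \times
\frac{(c+D)(e+F)}{(a+B)(g+H)}, \qquad
\mathrm{ICR}_{cc} = \mathrm{ICR}_{co} \times \frac{DF}{BH}.$$

The first multiplier is computed by `seor_cnc()`, the second appears in
`icr_cc()` and `seor_control()`. Each equals 1 exactly under S-E
independence in its population (full sample, controls), which is why the
case-only estimate can stand in for the others — and by exactly how much
it is off when independence fails. The test suite asserts both identities
to 1e-12 on random tables and on closed-form expected tables.

### A deliberate orientation choice

Both multipliers above are the *reciprocals* of the conventionally
oriented S-E odds ratios (concordant-over-discordant cells) that a
logistic fit of S on E reports. The literature on this method is not
consistent about which orientation it writes down, and the two differ
materially: multiplying the case-only ICR by the factor in the identity
recovers the full-sample ICR exactly, whereas multiplying by the
conventional OR moves the estimate the *wrong way* when the association
is real. This package resolves the ambiguity in favour of the exact
algebra: every S-E association quantity (`seor_cnc()`, `seor_control()`,
`fit_independence()`) is reported in the correction-factor orientation,
so that `icr_co * seor` is always the corrected full-sample estimate, and
each result carries the conventional OR alongside (`conventional_or`) for
reporting. The independence decision is orientation-invariant — an
interval contains 1 if and only if the reciprocal interval does — so no
decision changes under either convention. `adjust_icr()` and
`implied_case_only()` are pure arithmetic on whatever estimates they are
given; `implied_case_only()` accepts either orientation explicitly.

## The five-step workflow

`caseonly(D ~ S * E + covariates, data)` runs the procedure in the order
a practitioner reports it:

1. single-effect odds ratio for E (per one-unit difference);
2. single-effect odds ratio for S;
3. the full-sample interaction $e^{\beta_3}$;
4. the independence check in the full sample;
5. the case-only estimate — headline if step 4 passed, otherwise
   corrected by the S-E factor.

The default independence rule declares independence when the Wald interval
of the association contains 1. A stricter `"tolerance"` rule additionally
requires $|\log(\text{point})| \le \log(1+\varepsilon)$, because an
interval can contain 1 while the point estimate is far from it; the
literature's "close to 1" clause names no number, so $\varepsilon$ is left
to the user rather than silently invented. The corrected estimate is
computed and stored in *both* branches — it costs nothing, and a
borderline independence decision should never silently hide what the
correction would have done.

Two interval constructions are offered for the corrected estimate.
`"bound_product"` (default) multiplies the interval limits pairwise; it is
how this correction is customarily presented alongside the point product
and keeps the printed arithmetic reproducible to the digit. It has no
sampling-theory justification. `"lognormal_sum"` adds the log-scale
standard errors in quadrature — conventional, but it ignores the positive
covariance between the case-only estimate and the association factor
(they share the case data), so it is approximate too. Both are labelled in
the output; neither is hidden behind the other.

### Continuous susceptibility factors

The case-only model $\operatorname{logit} P(S=1) = \gamma_0 + \gamma_1 E$
is undefined when S is continuous, yet applied analyses routinely use
continuous susceptibility variables. Rather than silently fabricating an
estimator, the fitting functions refuse continuous S by default.
`continuous_s = "approximate"` enables a least-squares regression of S on
E (among cases, or in the full sample for the independence screen) and
reports `exp(slope)` flagged `"continuous-S approximation"`: a pragmatic,
clearly-labelled screen, not an odds ratio. The binary-S logistic path is
the supported estimator; dichotomization thresholds, where used, must
state their direction explicitly (`read_subjects()` refuses to infer
"abnormal" from the data).

## Diagnostics

**Rare-disease sensitivity.** Independence among *controls* is often all a
case-control study can check, but it is not the same condition as
independence in the full population. `seor_control_sensitivity()` gives
the exact bridge: with baseline risk $p_0 = P(D\mid S{-}E{-})$ and the
three relative risks against that reference,

$$\mathrm{OR}_{control} = \mathrm{OR}_{c/nc} \times
\frac{(1/p_0 - 1)(1/p_0 - \mathrm{RR}_{se})}
     {(1/p_0 - \mathrm{RR}_{s})(1/p_0 - \mathrm{RR}_{e})},$$

in the conventional orientation (the multiplier is orientation-specific;
take reciprocals of both sides for the correction-factor orientation).
The factor tends to 1 as $p_0 \to 0$; the grid defaults
($p_0$ from 0.1% to 6%, $\mathrm{RR}_s$ from 1 to 4) span the range over
which it visibly departs from 1. On an expected table with S-E
independence, the control-cell ratio $BH/(DF)$ reproduces this formula to
machine precision — the package tests exactly that. Some writings denote
the susceptibility relative risk $\mathrm{RR}_G$, a residue of the
gene-environment original; here it is `rr_s`.

**Stratification bias.** Hidden subpopulations with correlated S and E
prevalences create an S-E association in the pooled population even when
every stratum is internally independent. The induced bias on the
case-only route is approximately
$\mathrm{CIR} = r_{SE} \cdot CV_S \cdot CV_E + 1$ (`cir()`), with exact
bounds from the odds spread ratios (`cir_bounds()`): $U \ge 1$,
$L = 1/U$, and $U = L = 1$ whenever either odds shows no variation.
A point worth stating plainly, because loose accounts blur it: when the
disease model is shared across strata, stratification that shifts only
the S and E margins does *not* bias the full-sample logistic interaction
fit — $E[D \mid S, E]$ is unchanged — it biases the *case-only* route,
which absorbs the pooled S-E association. `cir_empirical()` therefore
defines the empirical CIR as the crude-over-stratum-adjusted *case-only*
estimate and returns both pairs of fits so the contrast is visible. The
stratum-level ingredients ($r_{SE}$, CVs, spreads) are size-weighted by
default, with unweighted variants available, since no operational
definition is standard.

**Efficiency.** `variance_comparison()` returns the three reciprocal-cell
asymptotic variances and their ratios; the case-only ratio is below 1 for
every table, which is the design's selling point made concrete.

## The simulator

`simulate_population()` draws a binary susceptibility factor and binary
exposure from the unique 2×2 joint distribution with given margins and
odds ratio (`joint_probs()`, the Plackett construction), then disease from
the logistic model above; strata and a normally distributed confounder
path (C shifting both S and E on the log-odds scale, inducing marginal
dependence with conditional independence) are available. Every draw flows
from one seed; identical parameters give identical populations.

Defaults describe the study the method is advertised for: n = 20,000
subjects, 30% prevalence of both factors, S-E independence, single
effects of 1.5 on the odds scale, no interaction, and a baseline risk of
$\operatorname{expit}(-5) \approx 0.7$% — a genuinely rare disease, the
regime in which odds ratios approximate risk ratios and the case-only
estimate targets the same quantity as $e^{\beta_3}$. The default seed,
20220929, is an arbitrary date-derived constant kept for reproducible
documentation.

`expected_table()` gives the closed-form expected 2×4 table, on which the
estimators hit their analytic targets exactly (e.g. the OR-basis
full-sample ICR equals $e^{\beta_3}$ to 1e-10); these are the oracles for
the identity tests. `recovery_experiment()` wraps replicated simulation
and reports bias and Monte-Carlo standard errors on the log scale —
ratio estimators are compared multiplicatively, and the arithmetic mean
of a ratio carries a Jensen term that the geometric mean does not — plus
Wald coverage and the empirical variance comparison. For binary S and E
it uses the closed-form table statistics, which coincide with the
saturated logistic maximum-likelihood fits (asserted to 1e-8 in the
suite). The validation experiments shipped in the tests use 200
replicates of n = 20,000, enough to resolve biases of a few percent while
keeping the suite quick.

What the simulator does **not** emulate — and hence what passing tests do
not certify about real data: continuous exposures and susceptibility
factors (the generator is binary; the continuous-S code path is exercised
by jittering), measurement error in S or E, missing-data mechanisms,
survey weights and complex sampling, time-varying exposure, and
case-selection artefacts. A real analysis inherits all of those on top of
the algebra verified here.

One subtlety the experiments surface honestly: the efficiency gain of the
case-only design equals the sum of reciprocal *non-case* counts, which is
small precisely in the rare-disease regime where the estimator is
unbiased for $e^{\beta_3}$. At 200 replicates the empirical variance
ordering is therefore a low-powered check — the Wald-variance ordering is
strict for every table, but its empirical counterpart resolves only
slowly. The suite runs it under the default conditions and seed and it
passes; expect it to be the first assertion to wobble if the conditions
are made more extreme.

## Numerical choices

* Closed-form intervals are log-Wald with variance equal to the sum of
  reciprocal contributing cells, consistent with the asymptotic variances
  of the three designs. No closed-form interval is offered for the
  table-based multiplicative full-sample ICR: its single-effect
  components share cells and the naive delta method is wrong. A seeded
  multinomial bootstrap (default 2000 resamples) or the saturated
  regression fit provides one.
* Zero cells: numerator zeros yield flagged zero estimates without
  intervals; denominator zeros are errors naming the cell. An optional
  Haldane-Anscombe +0.5 correction (`correct = TRUE`) is off by default
  and always flagged — never applied silently.
* Logistic fits run with convergence tolerance 1e-12 so saturated fits
  reproduce the closed-form estimators to 1e-8; a fitted log-scale
  coefficient beyond 15 triggers a separation flag and warning, with no
  silent penalization.
* Expected-value control sampling rounds half away from zero and warns on
  non-integer expected counts; binomial sampling is available, seeded.
* Estimates are kept at full precision internally; rounding to two
  decimals happens only in `format()`/`print()`.
* Reports serialize without wall-clock timestamps by default, so identical
  input, configuration and seed give byte-identical files.

## Known limitations

The case-only estimate is multiplicative-scale only; the additive RERI is
computed for full tables (point estimate only) but has no case-only
counterpart. No survey-weighted, penalized (Firth), exact-conditional or
Bayesian fits are provided. The continuous-S path is an explicit
approximation. Covariate adjustment in the case-only fit spends degrees
of freedom: adjusting for variables unrelated to the S-E dependence
costs precision for nothing, so covariates should earn their place.
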