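---
title: "Longitudinal bounded-count models for monthly migraine days"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal bounded-count models for monthly migraine days}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmdcount)
```

## The modelling problem

Migraine-prevention trials record, at each scheduled visit, the number of
migraine days a patient experienced over the preceding 28-day period — the
monthly migraine days (MMD), an integer in 0..28. Trials report cohort-level
mean changes, but economic evaluation needs the whole patient-level
*frequency distribution* at each time point: how many patients sit at 2, 8
or 20 days per month, since quality of life, medication use and costs scale
nonlinearly with frequency. `mmdcount` fits longitudinal parametric count
models to subject-visit MMD records, reconstructs the full 0..28
distribution per arm and visit from the fitted cohort parameters, and
extrapolates the mean trajectory beyond the trial window.

Two features of MMD data drive the model choices. First, counts are heavily
overdispersed: between-patient heterogeneity makes the variance several
times the mean. Second, the outcome is bounded above at 28, while the
standard count families are not.

## The four model families

All families share the same fixed covariate structure: an intercept, one
indicator per non-reference visit (reference = week 0) and a treatment
indicator, with no treatment-by-visit interaction. One record per
subject-visit enters the likelihood.

**Poisson** (reference model): mean `lambda_it = exp(x_it' beta)`, variance
equal to the mean. It systematically understates the spread of MMD data and
is included as the baseline comparator.

**Negative binomial (NB)**: mass function

    P(Y = k) = Gamma(k + tau) / (k! Gamma(tau)) *
               (tau / (tau + lambda))^tau * (lambda / (lambda + tau))^k

with variance `lambda + lambda^2 / tau`. The dispersion is held constant
over visits; the mean follows the log link. Two dispersion conventions
coexist in practice: the likelihood parameter `tau` above, and the
reciprocal `alpha = 1/tau` printed by most regression software. All
user-facing output of this package reports `alpha_report = 1/tau` (the
printed convention), with `tau` stored alongside; `nb_params()` accepts
either and keeps both consistent. The reported dispersion values around
0.1–0.25 for migraine cohorts are only plausible in this reciprocal
convention, which is why it is the display default.

**Beta-binomial (BB)**: the 28 days of a period are treated as 28
exchangeable binary outcomes whose success probability varies between
subject-visits according to a beta distribution with shapes `alpha`, `beta`:

    P(Y = k) = C(N, k) * B(alpha + k, beta + N - k) / B(alpha, beta),  N = 28

The intraclass correlation (ICC) among the daily outcomes is
`rho = 1 / (1 + alpha + beta)`, held constant over time, and the mean
proportion follows a logit link. `mean_icc_to_shapes()` converts a
(mean, ICC) pair to shapes via `alpha = p (1 - rho) / rho`,
`beta = (1 - p) (1 - rho) / rho` with `p = mu / N`; the round trip is exact.
The BB is inherently bounded at 28, which is its structural advantage for
this outcome. Estimation uses the grouped-count likelihood above — not a
day-expanded binary ("augmented") data layout — because the likelihood is
identical, far cheaper, and keeps the non-comparability of its likelihood
scale with the count families explicit (no AIC comparisons are offered
across families for this reason).

**Zero-inflated NB (ZINB)**: a structural-zero probability `pi` mixed with
the NB, `P(0) = pi + (1 - pi) NB(0)`, `P(k>0) = (1 - pi) NB(k)`. Trial
eligibility criteria exclude near-zero baselines, so inflation is typically
negligible in-trial; the family is provided for completeness and for
real-world populations where a genuine zero class exists.

### Bounding the unbounded families

NB, Poisson and ZINB place mass above 28. When a fitted model is mapped
back to a patient-level distribution, `truncated_pmf()` renormalises by
dividing each mass by the unbounded CDF at 28, so the reconstructed
distribution lives exactly on 0..28. For the ZINB the mixture is formed
first and then renormalised. Every renormalised mass is at least its
unbounded counterpart, and the vector sums to one to within 1e-12.

## Estimation

`fit_mmd()` maximises the analytic log-likelihood over the regression
coefficients and a transformed auxiliary parameter (`log tau`,
`logit rho`, `logit pi`) with L-BFGS-B from moment-based starting values
(Poisson or binomial GLM coefficients; method-of-moments dispersion/ICC),
followed by Newton polishing that drives the score norm to ~1e-8 when the
solution is interior. The transformed auxiliaries are box-bounded at +/-16,
so a Poisson-generated dataset drives `log tau` to its upper bound rather
than diverging; convergence is judged on the score norm (not the optimiser's
exit code) because a flat boundary direction can end the line search
abnormally at a perfectly good optimum. Non-convergence is always flagged
and warned about, never silent. Analytic scores are used for the Poisson,
NB and BB families; the ZINB uses central finite differences.

Parameter-level covariance is the inverse observed information
(`optimHess` at the optimum). Because observations within a subject are
correlated in real data, the default `variance_mode = "cluster-robust"`
additionally computes the subject-clustered sandwich `H^-1 M H^-1` with `M`
the sum of per-subject score outer products, scaled by `G/(G-1)` for `G`
subjects. On independently generated data the two agree (the test suite
checks the SE ratio is within 10% at 5600 observations).

The label "multilevel" for such models is ambiguous between cluster-robust
fixed effects and genuine random effects. The package's default is the
fixed-effects fit with cluster-robust SEs; a normal random intercept on the
link scale is available for the Poisson and NB families
(`random_intercept = TRUE`), integrated by adaptive Gauss-Hermite
quadrature: per-subject modes by damped Newton (the integrand is
log-concave), Laplace scaling, 15 nodes by default. The quadrature marginal
likelihood matches direct numerical integration to 1e-8 on fixture data,
and fixing the intercept SD at 0 reproduces the fixed-effects fit exactly.

## Predicted means, distributions and goodness of fit

`predict_mean()` returns the response-scale mean for an arm-visit cell
(`exp(eta)` for log links, `28 * invlogit(eta)` for the BB,
`(1 - pi) exp(eta)` for the ZINB, `exp(eta + sigma^2/2)` for random-
intercept log-link fits) with a 95% Wald interval from the delta method:
variance `g' V g` with `g` the response-scale gradient in the full
parameter vector. Intervals are reported unclamped so that pathological
fits remain visible. A 1000-replicate simulation in the acceptance suite
checks 94–96% coverage of the true week-0 mean.

`predict_distribution()` rebuilds the patient-level pmf of a cell from the
cohort fit: renormalised NB/Poisson/ZINB at the predicted mean and fitted
dispersion, or the exact BB at the predicted mean and fitted ICC.
`goodness_of_fit()` compares these reconstructions with the observed
histograms. RMSE and MAE are reported under *both* natural conventions —
pooled per-bin probability errors, and per-cell mean errors — because
"error across estimated values versus observations" can denote either, and
on a single error vector RMSE >= MAE always holds, so a report mixing
conventions cannot be reproduced from one vector. Both are always computed
and labelled; neither is privileged.

## Trajectory extrapolation

For economic modelling the per-arm mean trajectory is extended beyond the
trial window, to at most two years (104 weeks), after which no further
change is assumed. Four decreasing-to-plateau families are fitted to the
model-predicted means (raw cell means can be supplied instead) by
Levenberg-Marquardt least squares:

* exponential `m(t) = m_inf + (m_0 - m_inf) exp(-k t)`
* logistic `m(t) = m_inf + (m_0 - m_inf) (1 + exp(-k t_mid)) / (1 + exp(k (t - t_mid)))`
* log-logistic `m(t) = m_inf + (m_0 - m_inf) / (1 + (t/t_mid)^s)`
* Gompertz `m(t) = m_inf + (m_0 - m_inf) exp(-b (exp(c t) - 1))`

Each is anchored so that `m(0) = m_0` exactly. Parameters are bounded to
the feasible range (`m_0`, `m_inf` in [0, 28]; positive rates), starting
values come from the endpoints and the observed half-decay week, and a
constant series short-circuits to the exact degenerate fit. Selection is by
minimal SSE, with exact ties broken by fewer parameters and then a fixed
family order. Two numerical caveats are worth knowing: with only four
observed visits every 4-parameter family interpolates exactly, so selection
among them is then decided by floating-point residuals and the trajectory
should be read as interpolation rather than evidence for a family; and with
seven points under realistic noise the three sigmoid families are close to
indistinguishable by SSE. Extrapolated values are clamped to [0, 28] and
held constant past the horizon; uncertainty from the regression stage is
deliberately not propagated into the curves, matching how such
extrapolations are reported.

## The synthetic-trial simulator

`simulate_trial()` makes every other module testable without patient-level
data, which are not public for these studies. A `simulation_config()`
fixes the cohort design: subjects per arm, visit schedule, placebo mean
trajectory, a multiplicative treatment effect for the count families (an
additive logit shift for the BB), the generative family with its
dispersion/ICC/inflation, optional baseline-eligibility bounds, optional
monotone dropout, and a mandatory seed (identical seeds reproduce identical
datasets byte for byte).

`builtin_config()` mirrors the two study populations used throughout:

* **EM** (episodic migraine): 319 subjects per arm, visits every 4 weeks to
  week 24, placebo NB means 8.261 at week 0 declining to 6.421 at week 24,
  treatment FRR 0.761, dispersion 0.2397 (ICC 0.0297 and its logit-scale
  coefficient for the BB variant), baseline eligibility 4–14 MMD. The
  published per-visit output covers weeks 0, 4, 8, 12 and 24 while the
  observation count implies seven visits, so the week-16/20 means are
  linear interpolations of the week-12 and week-24 values — an assumption,
  fixed once here.
* **CM** (chronic migraine): 286 placebo / 190 active subjects, visits to
  week 12, placebo NB means 18.111 down to 13.997, FRR 0.828, dispersion
  0.1323 (BB: means 17.111 down to 14.894, ICC 0.1370), baseline >= 8 MMD.

The ZINB preset reuses the NB trajectory with a nominal `pi_zero = 0.02`,
since in-trial zero inflation was negligible and no separate ZINB
trajectory is published.

Two realism switches matter, and their defaults differ between the two
config constructors:

* `bound_counts = TRUE` (the `builtin_config()` default) re-draws NB,
  Poisson and ZINB values above 28 — re-draw rather than clamping, so no
  artificial spike accumulates at 28. This emulates the bounded outcome a
  real trial records, and is precisely the regime in which the unbounded NB
  model is misspecified: fitting the NB to capped chronic-scale data
  recovers *attenuated* pseudo-true parameters (the cap removes the long
  right tail, so the fitted mean and especially the fitted dispersion fall
  materially below the generative values; at episodic means the mass above
  28 is a fraction of a percent and the effect is negligible).
* Baseline eligibility re-draws only the week-0 count until it satisfies
  the bounds. This leaves post-baseline visits unbiased (counts are
  independent across visits, matching the fixed-effects likelihood), but
  compresses the week-0 variance, which also pulls a constant-dispersion
  fit below the generative dispersion.

For *parameter-recovery* experiments — whose purpose is to verify that the
estimators reproduce known generative values at the published trial scale —
the data must come from the exact model being refitted, so
`recovery_config()` switches both features off. `recovery_experiment()`
runs the full loop (simulate, refit, collect the dispersion or ICC, the
week-0 placebo delta-method mean and the treatment effect across seeds) and
`summary()` reports means, Monte-Carlo standard errors and standardised
deviations from the generative truth.

What passing these simulator-based tests does *not* show about real data:
the generator reproduces the marginal count model, the bounded outcome and
the eligibility screen, but not serial correlation within subjects beyond
the model's own structure, covariate effects (age, sex, race), informative
dropout, or the 70 mg arm. Conclusions about estimator calibration
transfer to real trials only insofar as the fitted family is adequate
there.

## Numerical and design choices, in brief

* All masses are computed in log space via `lgamma`/`lbeta`/`lchoose` and
  exponentiated last; 28-choose-k and small-`tau` terms overflow in direct
  form.
* Auxiliary parameters are estimated on transformed scales with box bounds
  at +/-16; iteration cap 500; score-based convergence declaration.
* An arm-by-visit cell with no observations drops that visit's indicator
  with a warning rather than producing an unidentified column.
* Wald 95% intervals throughout; FRRs are `exp(b)` with `exp(b +/- 1.96 se)`
  bounds for log links, while BB effects are reported on the coefficient
  (log-odds) scale, labelled as such.
* Counts above the period bound are rejected by the CSV reader with
  row-numbered messages; exact-model simulations may carry them and are
  constructed with validation relaxed.
* Test problem sizes are chosen to keep the default suite fast while
  leaving Monte-Carlo noise well below the tolerances tested: recovery
  experiments run 20 seeds at the published trial sizes, the coverage check
  runs 1000 replicates of a 300-subject, four-visit design, and reference
  cross-checks (against `MASS::glm.nb`, `glmmTMB`, `lme4::glmer`) use
  100–300 subjects.

## Known limitations

* No treatment-by-visit interactions; the treatment effect is a single
  multiplicative (or logit-additive) shift applied at every visit.
* The NB likelihood itself is not upper-bounded; the bound enters only at
  the distribution-reconstruction stage. A genuinely truncated-at-28 NB
  *likelihood* would be the natural next step for chronic cohorts, where
  the unbounded fit on bounded data is visibly attenuated.
* Extrapolation is a point exercise: regression uncertainty is not carried
  into the curves, and families are near-indistinguishable on short
  schedules.
* The random-intercept variant covers the log-link families only, and
  distribution reconstruction is defined for fixed-effects fits.
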