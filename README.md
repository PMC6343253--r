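# mmdcount

Longitudinal bounded-count models for monthly migraine days (MMD).

Migraine-prevention trials record, per subject and visit, the number of
migraine days in the preceding 28-day period — an overdispersed count
bounded in 0..28. Cohort-level mean changes are what trials report, but
health-economic models need the full patient-level frequency distribution
at each time point. `mmdcount` is for biostatisticians and modellers who
need to (i) fit longitudinal parametric count models to subject-visit MMD
records, (ii) reconstruct the complete 0..28 distribution per arm and visit
from the fitted cohort parameters, and (iii) extrapolate mean trajectories
beyond the trial window.

## Models

Four families over records `(subject, visit week, arm, count)`, each with
an intercept, per-visit indicators (reference week 0) and a treatment
indicator:

* **Poisson** — log link; the equidispersed reference model.
* **Negative binomial** — log link, constant dispersion; mass
  `P(Y=k) = Γ(k+τ)/(k! Γ(τ)) (τ/(τ+λ))^τ (λ/(λ+τ))^k`, variance
  `λ + λ²/τ`. Dispersion is displayed in the reporting convention
  `α = 1/τ`. Reconstructed distributions are renormalised onto 0..28 by
  dividing by the unbounded CDF at 28.
* **Beta-binomial** — the 28 days as correlated binary outcomes; logit
  link on the mean proportion, constant intraclass correlation
  `ρ = 1/(1+α+β)`; inherently bounded at 28.
* **Zero-inflated negative binomial** — structural-zero probability mixed
  with the NB, cluster-robust by default.

Fits are exact maximum likelihood (L-BFGS-B plus Newton polishing on
analytic scores), with subject-clustered sandwich covariance by default, an
optional adaptive Gauss–Hermite random intercept (Poisson/NB), delta-method
95% intervals for predicted means, RMSE/MAE goodness of fit under both the
bin-level and visit-mean conventions, and exponential / logistic /
log-logistic / Gompertz trajectory extrapolation with a two-year plateau.
A seedable simulator reproduces the episodic (EM) and chronic (CM) migraine
study designs so everything is testable without patient-level data.

## Worked example

```r
library(mmdcount)

cfg   <- builtin_config("EM", "negbin", seed = 42)  # 319/arm, weeks 0..24
trial <- simulate_trial(cfg)
fit   <- fit_mmd(trial, regression_spec("negbin"))
fit
#> Longitudinal negbin regression (log link)
#>   4466 observations, 638 subjects, visits: weeks 0,4,8,12,16,20,24 (ref 0)
#>   log-likelihood -11756.841, converged: TRUE
#>   dispersion (reporting convention) 0.2051
#>          term scale estimate  lower  upper   p_value
#> 1 (Intercept)   FRR   8.6641 8.3756 8.9626 0.000e+00
#> 2       week4   FRR   0.8305 0.7875 0.8758 7.281e-12
#> ...
#> 8   treatment   FRR   0.7744 0.7463 0.8036 9.720e-42
```

The intercept FRR is the week-0 placebo mean (8.66 days/28); the treatment
row says the active arm experiences 0.774 times the placebo frequency at
every visit. Note the fitted dispersion (0.205) sits below the generative
0.2397: this preset emulates the bounded trial reality — counts capped at
28 and a 4–14 baseline eligibility screen — under which the unbounded NB
is mildly misspecified. `recovery_config()` draws from the exact model
instead and recovers the generative values (see the vignette).

```r
predict_mean(fit, arm = 0, visit_week = 12)
#>   arm visit_week     mean        se    lower    upper
#> 1   0         12 6.500634 0.1821231 6.143672 6.857595

predict_distribution(fit, arm = 0, visit_week = 12)
#> Bounded count distribution (nb), support 0..28
#>   normalising constant (unbounded CDF at 28): 0.999872
#>   mean 6.498, P(0) = 0.0161, P(28) = 7.07e-05

goodness_of_fit(fit, trial)
#> Goodness of fit (negbin), 14 arm-by-visit cells
#>   bin-level:        RMSE 0.0140  MAE 0.0077
#>   visit-mean-level: RMSE 0.2867  MAE 0.1884
```

The delta-method interval for the week-12 placebo mean is 6.14–6.86 days;
the reconstructed distribution puts 1.6% of placebo patients at zero MMD.
Extrapolating the placebo trajectory to two years:

```r
tr   <- predicted_trajectory(fit, arms = 0)
best <- select_curve(fit_curves(tr$visit_week, tr$mean))
extrapolate(best, c(24, 52, 104, 200))
#>   week     mean
#> 1   24 6.292986
#> 2   52 6.262375
#> 3  104 6.256268
#> 4  200 6.256268   # plateau: constant beyond week 104
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/mmdcount`:

```sh
Rscript inst/cli/mmdcount simulate --preset em --seed 1 --out em.csv
Rscript inst/cli/mmdcount report --data em.csv --family negbin --out report/
```

Subcommands: `simulate`, `fit`, `predict`, `gof`, `extrapolate`, `report`
(exit 0 on success, 2 on malformed input with row-numbered messages).

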