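Package: mmdcount
Title: Longitudinal Bounded-Count Models for Monthly Migraine Days
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maximum-likelihood longitudinal regression for bounded count
    outcomes such as monthly migraine days (MMD, 0 to 28 days per 28-day
    period). Implements Poisson, negative-binomial (with renormalisation at
    the 28-day bound), beta-binomial (mean/intraclass-correlation
    parameterisation) and zero-inflated negative-binomial models with
    cluster-robust and random-intercept variants; delta-method confidence
    intervals for predicted means; reconstruction of full patient-level
    frequency distributions from fitted cohort parameters with RMSE/MAE
    goodness of fit; parametric extrapolation of mean trajectories
    (exponential, logistic, log-logistic, Gompertz) with a two-year plateau;
    and a seedable synthetic-trial simulator emulating episodic and chronic
    migraine study designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    MASS,
    lme4,
    glmmTMB
Config/testthat/edition: 3
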