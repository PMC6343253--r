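test_that("design matrix has the documented shape and coding", {
  d <- mmd_dataset(data.frame(subject_id = c("a", "a", "b", "b"),
                              visit_week = c(0, 4, 0, 4),
                              arm = c(0, 0, 1, 1),
                              mmd = c(3, 2, 5, 4)))
  des <- build_design(d, regression_spec("negbin"))
  expect_equal(dim(des$X), c(4, 3))
  expect_equal(colnames(des$X), c("(Intercept)", "week4", "treatment"))
  expect_equal(unname(des$X[1, ]), c(1, 0, 0))  # reference-visit placebo row
  expect_equal(unname(des$X[2, ]), c(1, 1, 0))
  expect_equal(unname(des$X[4, ]), c(1, 1, 1))
  # seven-visit schedule: intercept + six visit indicators + treatment
  cfg <- recovery_config("EM", "negbin", seed = 1)
  des7 <- build_design(simulate_trial(cfg), regression_spec("negbin"))
  expect_equal(ncol(des7$X), 8)
  expect_equal(colnames(des7$X)[2:7], paste0("week", c(4, 8, 12, 16, 20, 24)))
})

test_that("an empty visit-by-arm cell drops its indicator with a warning", {
  d <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 3),
                  visit_week = rep(c(0, 4, 8), 4),
                  arm = rep(c(0, 0, 1, 1), each = 3),
                  mmd = 5)
  d <- d[!(d$arm == 1 & d$visit_week == 8), ]  # no active subjects at week 8
  expect_warning(des <- build_design(mmd_dataset(d), regression_spec("negbin")),
                 "week 8")
  expect_false("week8" %in% colnames(des$X))
})

test_that("single-visit data cannot request visit indicators", {
  d <- data.frame(subject_id = c("a", "b"), visit_week = 0, arm = 0:1,
                  mmd = c(3, 4))
  expect_error(build_design(mmd_dataset(d), regression_spec("negbin")),
               "at least two")
})

test_that("intercept-only NB fit reproduces the sample mean", {
  cfg <- small_nb_config(seed = 21, n_per_arm = c(60, 60))
  d <- simulate_trial(cfg)
  f <- fit_mmd(d, regression_spec("negbin", covariates = "intercept",
                                  variance_mode = "model-based"))
  expect_equal(unname(exp(coef(f)[1])), mean(d$mmd), tolerance = 1e-6)
})

test_that("NB fit agrees with an independent reference implementation", {
  d <- simulate_trial(small_nb_config(seed = 31))
  f <- fit_mmd(d, regression_spec("negbin"))
  expect_true(f$converged)
  g <- MASS::glm.nb(mmd ~ factor(visit_week) + arm, data = as.data.frame(d))
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$aux$alpha_report, 1 / g$theta, tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("beta-binomial fit agrees with an independent reference implementation", {
  d <- simulate_trial(small_bb_config(seed = 32))
  f <- fit_mmd(d, regression_spec("betabin"))
  expect_true(f$converged)
  g <- glmmTMB::glmmTMB(cbind(mmd, 28 - mmd) ~ factor(visit_week) + arm,
                        family = glmmTMB::betabinomial(),
                        data = as.data.frame(d))
  expect_equal(unname(coef(f)), unname(glmmTMB::fixef(g)$cond),
               tolerance = 1e-4)
  expect_equal(f$aux$rho, 1 / (1 + glmmTMB::sigma(g)), tolerance = 1e-4)
})

test_that("zero-inflated NB fit agrees with an independent reference implementation", {
  cfg <- simulation_config("EM", c(120, 120), c(0, 4, 8),
                           c(8.261, 7.199, 6.731), 0.761, "frr", "zinb",
                           alpha_report = 0.2397, pi_zero = 0.1,
                           bound_counts = FALSE, seed = 33)
  d <- simulate_trial(cfg)
  f <- fit_mmd(d, regression_spec("zinb"))
  expect_true(f$converged)
  g <- glmmTMB::glmmTMB(mmd ~ factor(visit_week) + arm, ziformula = ~1,
                        family = glmmTMB::nbinom2, data = as.data.frame(d))
  expect_equal(unname(coef(f)), unname(glmmTMB::fixef(g)$cond),
               tolerance = 1e-4)
  expect_equal(f$aux$alpha_report, 1 / glmmTMB::sigma(g), tolerance = 1e-4)
  expect_equal(f$aux$pi_zero, unname(plogis(glmmTMB::fixef(g)$zi)),
               tolerance = 1e-4)
})

test_that("Poisson-generated data drive the NB dispersion to the boundary", {
  cfg <- simulation_config("EM", c(625, 625), c(0, 4), c(8.0, 7.0),
                           0.8, "frr", "poisson", bound_counts = FALSE,
                           seed = 34)
  d <- simulate_trial(cfg)  # 5000 observations
  fp <- fit_mmd(d, regression_spec("poisson"))
  fnb <- fit_mmd(d, regression_spec("negbin"))
  expect_lte(fnb$aux$alpha_report, 0.02)
  expect_equal(unname(coef(fnb)), unname(coef(fp)), tolerance = 1e-4)
  g <- glm(mmd ~ factor(visit_week) + arm, poisson(), as.data.frame(d))
  expect_equal(unname(coef(fp)), unname(coef(g)), tolerance = 1e-7)
})

test_that("log-likelihood matches per-observation mass oracles", {
  # single observation, geometric case: ln P(0; lam=2, tau=1) = ln(1/3)
  one <- mmd_dataset(data.frame(subject_id = "a", visit_week = 0, arm = 0,
                                mmd = 0))
  sp1 <- regression_spec("negbin", covariates = "intercept")
  expect_equal(mmd_loglik(one, sp1, coef = log(2), dispersion = 1), log(1 / 3),
               tolerance = 1e-12)
  # ten-row fixture: sum of individual log masses, all families
  d <- fixture10()
  beta <- c(1.9, -0.2, -0.3)
  lam <- exp(beta[1] - 0.2 * (d$visit_week == 4) - 0.3 * d$arm)
  nbo <- sum(log(mapply(function(k, l) nb_pmf(k, nb_params(l, tau = 4)),
                        d$mmd, lam)))
  expect_equal(mmd_loglik(d, regression_spec("negbin"), beta,
                          dispersion = 0.25), nbo, tolerance = 1e-10)
  po <- sum(log(mapply(function(k, l) poisson_pmf(k, l), d$mmd, lam)))
  expect_equal(mmd_loglik(d, regression_spec("poisson"), beta), po,
               tolerance = 1e-10)
  zo <- sum(log(mapply(function(k, l)
    zinb_pmf(k, zinb_params(l, tau = 4, pi_zero = 0.1)), d$mmd, lam)))
  expect_equal(mmd_loglik(d, regression_spec("zinb"), beta, dispersion = 0.25,
                          pi_zero = 0.1), zo, tolerance = 1e-10)
  pbb <- plogis(qlogis(0.3) - 0.2 * (d$visit_week == 4) - 0.3 * d$arm)
  bbo <- sum(log(mapply(function(k, pr)
    bb_pmf(k, mean_icc_to_shapes(28 * pr, 0.1, 28)), d$mmd, pbb)))
  expect_equal(mmd_loglik(d, regression_spec("betabin"),
                          c(qlogis(0.3), -0.2, -0.3), rho = 0.1), bbo,
               tolerance = 1e-10)
})

test_that("the maximised likelihood dominates the generative-truth likelihood", {
  for (s in 1:3) {
    d <- simulate_trial(small_nb_config(seed = 40 + s, n_per_arm = c(80, 80)))
    f <- fit_mmd(d, regression_spec("negbin"))
    truth_ll <- mmd_loglik(d, regression_spec("negbin"),
                           coef = c(log(8.261), log(7.199 / 8.261),
                                    log(6.731 / 8.261), log(6.4337 / 8.261),
                                    log(0.761)),
                           dispersion = 0.2397)
    expect_gte(f$loglik, truth_ll)
  }
  d <- simulate_trial(small_bb_config(seed = 44, n_per_arm = c(80, 80)))
  f <- fit_mmd(d, regression_spec("betabin"))
  truth_ll <- mmd_loglik(d, regression_spec("betabin"),
                         coef = c(qlogis(7.945 / 28),
                                  qlogis(7.080 / 28) - qlogis(7.945 / 28),
                                  qlogis(6.672 / 28) - qlogis(7.945 / 28),
                                  qlogis(6.386 / 28) - qlogis(7.945 / 28),
                                  -0.327),
                         rho = 0.0297)
  expect_gte(f$loglik, truth_ll)
})

test_that("cluster-robust and model-based SEs agree on independent data", {
  cfg <- small_nb_config(seed = 50, n_per_arm = c(700, 700))
  cfg$visit_weeks <- c(0, 4); cfg$placebo_means <- c(8.261, 7.199)
  d <- simulate_trial(do.call(simulation_config, unclass(cfg)))  # 2800 obs
  f <- fit_mmd(d, regression_spec("negbin"))
  r <- sqrt(diag(vcov(f, "cluster-robust")) / diag(vcov(f, "model-based")))
  expect_true(all(abs(r - 1) < 0.10))
})

test_that("frequency rate ratios exponentiate log-link fits and label logit fits", {
  d <- simulate_trial(small_nb_config(seed = 51, n_per_arm = c(60, 60)))
  f <- fit_mmd(d, regression_spec("negbin"))
  frr <- frequency_rate_ratios(f)
  expect_equal(frr$estimate, unname(exp(coef(f))), tolerance = 1e-12)
  se <- sqrt(diag(vcov(f)))
  expect_equal(frr$lower, unname(exp(coef(f) - 1.96 * se)), tolerance = 1e-12)
  expect_true(all(frr$scale == "FRR"))
  db <- simulate_trial(small_bb_config(seed = 52, n_per_arm = c(60, 60)))
  fb <- fit_mmd(db, regression_spec("betabin"))
  frrb <- frequency_rate_ratios(fb)
  expect_true(all(frrb$scale == "coefficient"))
  expect_equal(frrb$estimate, unname(coef(fb)), tolerance = 1e-12)
})

test_that("an all-zero response is rejected for dispersion families", {
  d <- mmd_dataset(data.frame(subject_id = rep(c("a", "b"), each = 2),
                              visit_week = rep(c(0, 4), 2),
                              arm = c(0, 0, 1, 1), mmd = 0L))
  expect_error(fit_mmd(d, regression_spec("negbin")), "all-zero")
})
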