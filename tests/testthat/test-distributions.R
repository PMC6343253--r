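test_that("negative-binomial mass matches the geometric case and a recursion oracle", {
  # tau = 1 is geometric: P(0) = tau/(tau+lam)
  expect_equal(nb_pmf(0, nb_params(2, tau = 1)), 1 / 3, tolerance = 1e-12)
  # forward recursion P(k) = P(k-1) (k-1+tau)/k * lam/(lam+tau), independent
  # of the log-gamma evaluation
  p <- nb_params(8.261, alpha_report = 0.2397)
  rec <- numeric(21)
  rec[1] <- (p$tau / (p$tau + p$lam))^p$tau
  for (k in 1:20)
    rec[k + 1] <- rec[k] * (k - 1 + p$tau) / k * p$lam / (p$lam + p$tau)
  expect_equal(nb_pmf(0:20, p), rec, tolerance = 1e-12)
  expect_equal(nb_pmf(8, p), rec[9], tolerance = 1e-12)
  # and against the standard parameterisation in stats
  expect_equal(nb_pmf(0:20, p), dnbinom(0:20, size = p$tau, mu = p$lam),
               tolerance = 1e-12)
})

test_that("every family normalises over its support", {
  p <- nb_params(8.261, alpha_report = 0.2397)
  expect_equal(sum(nb_pmf(0:10000, p)), 1, tolerance = 1e-10)
  z <- zinb_params(5, tau = 2, pi_zero = 0.2)
  expect_equal(sum(zinb_pmf(0:10000, z)), 1, tolerance = 1e-10)
  expect_equal(sum(poisson_pmf(0:200, 8.333)), 1, tolerance = 1e-10)
  bb <- mean_icc_to_shapes(17.111, 0.137)
  expect_equal(sum(bb_pmf(0:28, bb)), 1, tolerance = 1e-12)
})

test_that("poisson mass matches its recursion oracle and the NB large-tau limit", {
  expect_equal(poisson_pmf(0, 1), exp(-1), tolerance = 1e-12)
  lam <- 8.333
  rec <- numeric(13); rec[1] <- exp(-lam)
  for (k in 1:12) rec[k + 1] <- rec[k] * lam / k
  expect_equal(poisson_pmf(0:12, lam), rec, tolerance = 1e-12)
  expect_equal(nb_pmf(0:40, nb_params(lam, tau = 1e6)),
               poisson_pmf(0:40, lam), tolerance = 1e-5)
})

test_that("bounded renormalisation divides by the unbounded CDF and dominates it", {
  p <- nb_params(18.111, alpha_report = 0.1323)
  tp <- truncated_pmf(p, 28)
  expect_length(tp$prob, 29)
  expect_equal(sum(tp$prob), 1, tolerance = 1e-12)
  # brute-force CDF oracle
  cdf28 <- sum(nb_pmf(0:28, p))
  expect_equal(tp$prob[29] / nb_pmf(28, p), 1 / cdf28, tolerance = 1e-10)
  expect_equal(tp$norm_const, cdf28, tolerance = 1e-12)
  expect_true(all(tp$prob >= nb_pmf(0:28, p)))
  # degenerate small-mean limit
  expect_equal(truncated_pmf(nb_params(0.01, tau = 1))$prob[1], 1,
               tolerance = 1e-2)
  # zero-inflated: mixture first, then renormalise
  z <- zinb_params(18.111, alpha_report = 0.1323, pi_zero = 0.1)
  tz <- truncated_pmf(z)
  expect_equal(tz$prob, zinb_pmf(0:28, z) / sum(zinb_pmf(0:28, z)),
               tolerance = 1e-12)
})

test_that("beta-binomial mass: uniform case, binomial limit, quadrature oracle", {
  u <- bb_params(1, 1, 28)
  expect_equal(bb_pmf(0:28, u), rep(1 / 29, 29), tolerance = 1e-12)
  near_bin <- mean_icc_to_shapes(8, 1e-8, 28)
  expect_equal(bb_pmf(0:28, near_bin), dbinom(0:28, 28, 8 / 28),
               tolerance = 1e-4)
  # numerical quadrature over the mixing beta density
  p <- mean_icc_to_shapes(7.945, 0.0297, 28)
  q8 <- integrate(function(x) dbinom(8, 28, x) * dbeta(x, p$alpha, p$beta),
                  0, 1, rel.tol = 1e-12)$value
  expect_equal(bb_pmf(8, p), q8, tolerance = 1e-10)
})

test_that("beta-binomial agrees with enumeration over exchangeable day patterns", {
  # augmented-Bernoulli oracle: each of the 2^N daily on/off patterns has
  # probability integral p^s (1-p)^(N-s) over the mixing beta, by quadrature
  p <- mean_icc_to_shapes(2.2, 0.21, 6)
  for (N in c(4, 6)) {
    pp <- mean_icc_to_shapes(p$mu * N / 6, p$rho, N)
    patterns <- as.matrix(expand.grid(rep(list(0:1), N)))
    s <- rowSums(patterns)
    seq_prob <- vapply(s, function(si)
      integrate(function(x) x^si * (1 - x)^(N - si) *
                  dbeta(x, pp$alpha, pp$beta), 0, 1, rel.tol = 1e-12)$value,
      numeric(1))
    oracle <- vapply(0:N, function(k) sum(seq_prob[s == k]), numeric(1))
    expect_equal(bb_pmf(0:N, pp), oracle, tolerance = 1e-10)
  }
})

test_that("mean/ICC and shape parameterisations round-trip exactly", {
  expect_equal(mean_icc_to_shapes(14, 0.5, 28)$alpha, 0.5, tolerance = 1e-12)
  expect_equal(mean_icc_to_shapes(14, 0.5, 28)$beta, 0.5, tolerance = 1e-12)
  for (mu in c(0.5, 7.945, 17.111, 27)) {
    for (rho in c(0.001, 0.0297, 0.137, 0.9)) {
      sh <- mean_icc_to_shapes(mu, rho, 28)
      expect_equal(1 / (1 + sh$alpha + sh$beta), rho, tolerance = 1e-12)
      expect_equal(sh$mu, mu, tolerance = 1e-12)
      m <- params_moments(sh)
      expect_equal(unname(m["mean"]), mu, tolerance = 1e-12)
      pr <- mu / 28
      expect_equal(unname(m["variance"]),
                   28 * pr * (1 - pr) * (1 + 27 * rho), tolerance = 1e-12)
    }
  }
})

test_that("zero-inflated mass mixes correctly", {
  nb <- nb_params(5, tau = 2)
  expect_equal(zinb_pmf(0:30, zinb_params(5, tau = 2, pi_zero = 0)),
               nb_pmf(0:30, nb), tolerance = 1e-14)
  expect_equal(zinb_pmf(0, zinb_params(5, tau = 2, pi_zero = 1 - 1e-9)), 1,
               tolerance = 1e-8)
  # hand arithmetic: NB(0) = (tau/(tau+lam))^tau = (2/7)^2
  expect_equal(zinb_pmf(0, zinb_params(5, tau = 2, pi_zero = 0.2)),
               0.2 + 0.8 * (2 / 7)^2, tolerance = 1e-12)
})

test_that("overdispersion orderings hold", {
  for (lam in c(2, 8.261, 18.111)) {
    for (tau in c(0.5, 4, 50)) {
      m <- params_moments(nb_params(lam, tau = tau))
      expect_gt(m["variance"], lam)
      expect_equal(unname(m["variance"]), lam + lam^2 / tau, tolerance = 1e-12)
    }
  }
  pr <- 8 / 28
  bin_var <- 28 * pr * (1 - pr)
  expect_gt(params_moments(mean_icc_to_shapes(8, 0.1, 28))["variance"], bin_var)
  expect_equal(unname(params_moments(mean_icc_to_shapes(8, 1e-9, 28))["variance"]),
               bin_var, tolerance = 1e-6)
})

test_that("domain and parameter errors are raised", {
  expect_error(nb_pmf(-1, nb_params(2, tau = 1)), "non-negative")
  expect_error(nb_pmf(2.5, nb_params(2, tau = 1)), "integer")
  expect_error(nb_params(-1, tau = 1))
  expect_error(nb_params(2, tau = -1))
  expect_error(nb_params(2, tau = 1, alpha_report = 1), "exactly one")
  expect_error(bb_pmf(29, bb_params(1, 1, 28)), "exceed")
  expect_error(mean_icc_to_shapes(28, 0.1, 28), "strictly inside")
  expect_error(mean_icc_to_shapes(5, 1, 28), "strictly inside")
  expect_error(zinb_params(5, tau = 2, pi_zero = 1), "pi_zero")
  expect_error(truncated_pmf(bb_params(1, 1, 28), n_max = 20), "n_days")
})
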