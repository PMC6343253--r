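#' Negative-binomial parameter bundle
#'
#' Bundles the mean and dispersion of a negative-binomial count model in both
#' conventions used for monthly migraine-day (MMD) data: the likelihood
#' dispersion `tau` (variance `lam + lam^2/tau`) and the reporting convention
#' `alpha_report = 1/tau` printed by most regression software. Exactly one of
#' `tau` or `alpha_report` must be supplied.
#'
#' @param lam Mean events per 28-day period (`> 0`).
#' @param tau Likelihood dispersion (`> 0`); large `tau` approaches Poisson.
#' @param alpha_report Reporting-convention dispersion (`= 1/tau`, `> 0`).
#' @return An object of class `nb_params` with fields `lam`, `tau`,
#'   `alpha_report`.
#' @examples
#' p <- nb_params(lam = 8.261, alpha_report = 0.2397)
#' p$tau * p$alpha_report  # 1
#' @export
nb_params <- function(lam, tau = NULL, alpha_report = NULL) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam), lam > 0)
  if (is.null(tau) == is.null(alpha_report))
    stop("supply exactly one of `tau` or `alpha_report`")
  if (is.null(tau)) {
    stopifnot(is.numeric(alpha_report), alpha_report > 0)
    tau <- 1 / alpha_report
  } else {
    stopifnot(is.numeric(tau), tau > 0)
    alpha_report <- 1 / tau
  }
  structure(list(lam = lam, tau = tau, alpha_report = alpha_report),
            class = c("nb_params", "mmd_params"))
}

#' Beta-binomial parameter bundle
#'
#' A beta-binomial over `n_days` daily binary outcomes with beta shapes
#' `alpha`, `beta`. The induced mean count is `mu = n_days * alpha /
#' (alpha + beta)` and the intraclass correlation (ICC) among the daily
#' outcomes is `rho = 1 / (1 + alpha + beta)`.
#'
#' @param alpha,beta Beta shape parameters (`> 0`).
#' @param n_days Period length (positive integer, default 28).
#' @return An object of class `bb_params` with fields `alpha`, `beta`,
#'   `n_days`, `mu`, `rho`.
#' @seealso [mean_icc_to_shapes()] for the inverse (mean/ICC) construction.
#' @export
bb_params <- function(alpha, beta, n_days = 28L) {
  stopifnot(is.numeric(alpha), alpha > 0, is.numeric(beta), beta > 0,
            n_days >= 1, n_days == round(n_days))
  structure(list(alpha = alpha, beta = beta, n_days = as.integer(n_days),
                 mu = n_days * alpha / (alpha + beta),
                 rho = 1 / (1 + alpha + beta)),
            class = c("bb_params", "mmd_params"))
}

#' Convert a mean/ICC pair to beta-binomial shapes
#'
#' Inverts the moment map of the beta-binomial: given the mean count `mu`
#' (days per period) and the intraclass correlation `rho`, returns the beta
#' shapes `alpha = p * (1 - rho) / rho` and `beta = (1 - p) * (1 - rho) / rho`
#' with `p = mu / n_days`. The round trip `rho = 1 / (1 + alpha + beta)` and
#' `mu = n_days * alpha / (alpha + beta)` is exact.
#'
#' @param mu Mean count, strictly between 0 and `n_days`.
#' @param rho ICC, strictly inside (0, 1).
#' @param n_days Period length (default 28).
#' @return A [bb_params()] object.
#' @examples
#' mean_icc_to_shapes(7.945, 0.0297)  # EM-scale shapes
#' @export
mean_icc_to_shapes <- function(mu, rho, n_days = 28L) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(rho), length(rho) == 1L)
  if (!(mu > 0 && mu < n_days)) stop("`mu` must lie strictly inside (0, n_days)")
  if (!(rho > 0 && rho < 1)) stop("`rho` must lie strictly inside (0, 1)")
  p <- mu / n_days
  theta <- (1 - rho) / rho
  bb_params(alpha = p * theta, beta = (1 - p) * theta, n_days = n_days)
}

#' Zero-inflated negative-binomial parameter bundle
#'
#' @param lam,tau,alpha_report As in [nb_params()].
#' @param pi_zero Structural-zero probability, in `[0, 1)`.
#' @return An object of class `zinb_params`.
#' @export
zinb_params <- function(lam, tau = NULL, alpha_report = NULL, pi_zero) {
  nb <- nb_params(lam, tau = tau, alpha_report = alpha_report)
  stopifnot(is.numeric(pi_zero), length(pi_zero) == 1L)
  if (!(pi_zero >= 0 && pi_zero < 1)) stop("`pi_zero` must lie in [0, 1)")
  structure(c(unclass(nb), list(pi_zero = pi_zero)),
            class = c("zinb_params", "mmd_params"))
}

#' Poisson parameter bundle
#'
#' @param lam Mean events per period (`> 0`).
#' @return An object of class `pois_params`.
#' @export
pois_params <- function(lam) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam), lam > 0)
  structure(list(lam = lam), class = c("pois_params", "mmd_params"))
}

check_counts <- function(k, upper = Inf) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0) || any(k != round(k)))
    stop("counts must be non-negative integers")
  if (any(k > upper)) stop("counts must not exceed ", upper)
  invisible(as.integer(round(k)))
}

#' Negative-binomial probability mass
#'
#' Mass function of the negative binomial in its mean/dispersion form,
#' `P(Y = k) = Gamma(k + tau) / (k! Gamma(tau)) *
#' (tau / (tau + lam))^tau * (lam / (lam + tau))^k`,
#' evaluated in log space via `lgamma` and exponentiated last.
#'
#' @param k Non-negative integer count(s).
#' @param params An [nb_params()] object.
#' @param log If `TRUE`, return the log mass.
#' @return Probabilities (or log probabilities), vectorised over `k`.
#' @export
nb_pmf <- function(k, params, log = FALSE) {
  stopifnot(inherits(params, "nb_params"))
  k <- check_counts(k)
  lam <- params$lam; tau <- params$tau
  lp <- lgamma(k + tau) - lgamma(tau) - lgamma(k + 1) +
    tau * (log(tau) - log(tau + lam)) +
    k * (log(lam) - log(lam + tau))
  if (log) lp else exp(lp)
}

#' Beta-binomial probability mass
#'
#' `P(Y = k) = choose(N, k) * B(alpha + k, beta + N - k) / B(alpha, beta)`,
#' computed via `lchoose`/`lbeta`.
#'
#' @param k Integer count(s) in `0..n_days`.
#' @param params A [bb_params()] object.
#' @param log If `TRUE`, return the log mass.
#' @return Probabilities, vectorised over `k`.
#' @export
bb_pmf <- function(k, params, log = FALSE) {
  stopifnot(inherits(params, "bb_params"))
  k <- check_counts(k, upper = params$n_days)
  N <- params$n_days; a <- params$alpha; b <- params$beta
  lp <- lchoose(N, k) + lbeta(a + k, b + N - k) - lbeta(a, b)
  if (log) lp else exp(lp)
}

#' Zero-inflated negative-binomial probability mass
#'
#' Mixture of a point mass at zero (probability `pi_zero`) with a negative
#' binomial: `P(0) = pi + (1 - pi) NB(0)`, `P(k > 0) = (1 - pi) NB(k)`.
#'
#' @param k Non-negative integer count(s).
#' @param params A [zinb_params()] object.
#' @return Probabilities, vectorised over `k`.
#' @export
zinb_pmf <- function(k, params) {
  stopifnot(inherits(params, "zinb_params"))
  k <- check_counts(k)
  nb <- nb_pmf(k, nb_params(params$lam, tau = params$tau))
  ifelse(k == 0, params$pi_zero + (1 - params$pi_zero) * nb,
         (1 - params$pi_zero) * nb)
}

#' Poisson probability mass
#'
#' @param k Non-negative integer count(s).
#' @param lam Mean (`> 0`), or a [pois_params()] object.
#' @return Probabilities, vectorised over `k`.
#' @export
poisson_pmf <- function(k, lam) {
  if (inherits(lam, "pois_params")) lam <- lam$lam
  stopifnot(is.numeric(lam), lam > 0)
  k <- check_counts(k)
  stats::dpois(k, lam)
}

untruncated_pmf <- function(params, k) {
  switch(class(params)[1],
         nb_params = nb_pmf(k, params),
         zinb_params = zinb_pmf(k, params),
         pois_params = poisson_pmf(k, params),
         bb_params = bb_pmf(k, params),
         stop("unsupported parameter class"))
}

#' Renormalise a count distribution onto the bounded support 0..n_max
#'
#' Divides each unbounded mass by the unbounded CDF at `n_max` so the
#' resulting distribution lives on `0..n_max` and sums to one. This is the
#' renormalisation used to map an unbounded negative-binomial (or Poisson, or
#' zero-inflated negative-binomial) fit onto the 0-28 migraine-day scale; a
#' beta-binomial is already bounded, so its method returns the exact mass with
#' normalising constant 1.
#'
#' @param params A parameter bundle (`nb_params`, `pois_params`,
#'   `zinb_params` or `bb_params`).
#' @param n_max Upper support bound (default 28).
#' @return An object of class `truncated_pmf`: list with integer support `k`,
#'   `prob` (sums to 1), `family`, and `norm_const` (the unbounded CDF at
#'   `n_max`).
#' @examples
#' tp <- truncated_pmf(nb_params(8.261, alpha_report = 0.2397))
#' sum(tp$prob)
#' @export
truncated_pmf <- function(params, n_max = 28L) {
  stopifnot(inherits(params, "mmd_params"), n_max >= 1, n_max == round(n_max))
  n_max <- as.integer(n_max)
  if (inherits(params, "bb_params")) {
    if (params$n_days != n_max)
      stop("beta-binomial support is fixed by `n_days`; got n_max != n_days")
    p <- bb_pmf(0:n_max, params)
    z <- 1
  } else {
    raw <- untruncated_pmf(params, 0:n_max)
    z <- sum(raw)
    p <- raw / z
  }
  structure(list(k = 0:n_max, prob = p,
                 family = sub("_params$", "", class(params)[1]),
                 norm_const = z),
            class = "truncated_pmf")
}

#' @export
as.data.frame.truncated_pmf <- function(x, ...) {
  data.frame(k = x$k, probability = x$prob)
}

#' @export
print.truncated_pmf <- function(x, ...) {
  cat(sprintf("Bounded count distribution (%s), support 0..%d\n",
              x$family, max(x$k)))
  cat(sprintf("  normalising constant (unbounded CDF at %d): %.6f\n",
              max(x$k), x$norm_const))
  cat(sprintf("  mean %.3f, P(0) = %.4f, P(%d) = %.4g\n",
              sum(x$k * x$prob), x$prob[1], max(x$k), x$prob[length(x$prob)]))
  invisible(x)
}

#' Moments of a parameter bundle
#'
#' Mean and variance implied by a count-family parameter bundle: Poisson
#' `lam`/`lam`; negative binomial `lam`/`lam + lam^2/tau`; beta-binomial
#' `mu` and `N p (1-p) (1 + (N-1) rho)`; zero-inflated negative binomial by
#' the standard mixture formulas.
#'
#' @param params A parameter bundle.
#' @return Named numeric vector `c(mean, variance)`.
#' @export
params_moments <- function(params) {
  stopifnot(inherits(params, "mmd_params"))
  if (inherits(params, "nb_params") && !inherits(params, "zinb_params")) {
    m <- params$lam; v <- params$lam + params$lam^2 / params$tau
  } else if (inherits(params, "zinb_params")) {
    w <- 1 - params$pi_zero
    m <- w * params$lam
    ex2 <- w * (params$lam + params$lam^2 / params$tau + params$lam^2)
    v <- ex2 - m^2
  } else if (inherits(params, "bb_params")) {
    p <- params$mu / params$n_days
    m <- params$mu
    v <- params$n_days * p * (1 - p) * (1 + (params$n_days - 1) * params$rho)
  } else {
    m <- v <- params$lam
  }
  c(mean = m, variance = v)
}
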