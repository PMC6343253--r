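# Decreasing-to-plateau trajectory families for the mean MMD over weeks.
# All four satisfy m(0) = m_0 and m(t) -> m_inf:
#   exponential  m(t) = m_inf + (m_0 - m_inf) exp(-rate t)
#   logistic     m(t) = m_inf + (m_0 - m_inf) (1 + exp(-rate t_mid)) /
#                                (1 + exp(rate (t - t_mid)))
#   log-logistic m(t) = m_inf + (m_0 - m_inf) / (1 + (t / t_mid)^shape)
#   gompertz     m(t) = m_inf + (m_0 - m_inf) exp(-b (exp(c t) - 1))

curve_families <- c("exponential", "logistic", "loglogistic", "gompertz")

curve_npar <- c(exponential = 3L, logistic = 4L, loglogistic = 4L,
                gompertz = 4L)

curve_eval <- function(family, par, t) {
  d <- par[["m_0"]] - par[["m_inf"]]
  par[["m_inf"]] + switch(family,
    exponential = d * exp(-par[["rate"]] * t),
    logistic = d * (1 + exp(-par[["rate"]] * par[["t_mid"]])) /
      (1 + exp(par[["rate"]] * (t - par[["t_mid"]]))),
    loglogistic = d / (1 + (t / par[["t_mid"]])^par[["shape"]]),
    gompertz = d * exp(-par[["b"]] * (exp(par[["c"]] * t) - 1)))
}

curve_bounds <- function(family, t_max) {
  lw <- c(m_inf = 0, m_0 = 0)
  up <- c(m_inf = 28, m_0 = 28)
  switch(family,
    exponential = list(lower = c(lw, rate = 1e-6),
                       upper = c(up, rate = 10)),
    logistic = list(lower = c(lw, rate = 1e-6, t_mid = -2 * t_max),
                    upper = c(up, rate = 10, t_mid = 2 * t_max)),
    loglogistic = list(lower = c(lw, t_mid = 1e-2, shape = 0.1),
                       upper = c(up, t_mid = 10 * t_max, shape = 20)),
    gompertz = list(lower = c(lw, b = 1e-8, c = 1e-4),
                    upper = c(up, b = 100, c = 2)))
}

curve_start <- function(family, weeks, means) {
  m0 <- means[1]; minf <- means[length(means)]
  half <- (m0 + minf) / 2
  t_half <- if (m0 > minf) {
    i <- which(means <= half)[1]
    if (is.na(i) || i == 1) stats::median(weeks[-1]) else weeks[i]
  } else stats::median(weeks[-1])
  t_half <- max(t_half, 1)
  k0 <- log(2) / t_half
  switch(family,
    exponential = c(m_inf = minf, m_0 = m0, rate = k0),
    logistic = c(m_inf = minf, m_0 = m0, rate = k0, t_mid = t_half),
    loglogistic = c(m_inf = minf, m_0 = m0, t_mid = t_half, shape = 2),
    gompertz = c(m_inf = minf, m_0 = m0,
                 b = log(2) / max(exp(k0 * t_half) - 1, 1e-6), c = k0))
}

#' Fit a parametric mean-trajectory curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of one of four
#' decreasing-to-plateau families to a per-arm mean MMD trajectory, typically
#' the model-predicted means from [predicted_trajectory()]. A constant series
#' is handled exactly (`m_0 = m_inf =` the constant, SSE 0).
#'
#' @param weeks Strictly increasing, non-negative observation weeks.
#' @param means Mean counts at those weeks (same length).
#' @param family One of `"exponential"`, `"logistic"`, `"loglogistic"`,
#'   `"gompertz"`.
#' @param horizon_weeks Plateau horizon carried into [extrapolate()]
#'   (default 104, i.e. two years).
#' @return An object of class `curve_fit`: `family`, named `par`, `sse`,
#'   `fitted`, `converged`, `se` (parameter standard errors where available),
#'   `horizon_weeks`.
#' @export
fit_curve <- function(weeks, means, family = c("exponential", "logistic",
                                               "loglogistic", "gompertz"),
                      horizon_weeks = 104) {
  family <- match.arg(family)
  stopifnot(length(weeks) == length(means), all(is.finite(weeks)),
            all(is.finite(means)), all(weeks >= 0))
  if (any(diff(weeks) <= 0)) stop("weeks must be strictly increasing")
  npar <- curve_npar[[family]]
  if (length(weeks) < npar)
    stop(sprintf("%s needs at least %d points, got %d", family, npar,
                 length(weeks)))
  if (diff(range(means)) < 1e-12) {
    par <- curve_start(family, weeks, means)
    par[["m_0"]] <- par[["m_inf"]] <- means[1]
    return(new_curve_fit(family, par, weeks, means, converged = TRUE,
                         se = rep(NA_real_, npar), horizon_weeks))
  }
  start <- curve_start(family, weeks, means)
  bounds <- curve_bounds(family, max(weeks))
  resid_fn <- function(p) means - curve_eval(family, as.list(p), weeks)
  fit <- try(minpack.lm::nls.lm(
    par = start, lower = bounds$lower, upper = bounds$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    opt <- stats::optim(start, function(p) sum(resid_fn(p)^2),
                        method = "L-BFGS-B", lower = bounds$lower,
                        upper = bounds$upper, control = list(maxit = 1000))
    return(new_curve_fit(family, opt$par, weeks, means,
                         converged = opt$convergence == 0,
                         se = rep(NA_real_, npar), horizon_weeks))
  }
  se <- rep(NA_real_, npar)
  cov <- try(chol2inv(chol(fit$hessian)) * fit$deviance /
               max(length(weeks) - npar, 1), silent = TRUE)
  if (!inherits(cov, "try-error")) se <- sqrt(pmax(2 * diag(cov), 0))
  names(se) <- names(start)
  new_curve_fit(family, fit$par, weeks, means,
                converged = fit$info %in% 1:4, se = se, horizon_weeks)
}

new_curve_fit <- function(family, par, weeks, means, converged, se,
                          horizon_weeks) {
  par <- unlist(par)
  fitted <- curve_eval(family, as.list(par), weeks)
  structure(list(family = family, par = par, sse = sum((means - fitted)^2),
                 fitted = fitted, weeks = weeks, means = means,
                 converged = converged, se = se,
                 horizon_weeks = horizon_weeks),
            class = "curve_fit")
}

#' Fit all four trajectory families
#'
#' @inheritParams fit_curve
#' @param families Subset of the four family names.
#' @return A named list of [fit_curve()] results (errors for families with
#'   too few points are dropped with a warning).
#' @export
fit_curves <- function(weeks, means, families = curve_families,
                       horizon_weeks = 104) {
  out <- list()
  for (f in families) {
    r <- try(fit_curve(weeks, means, f, horizon_weeks), silent = TRUE)
    if (inherits(r, "try-error")) warning("family ", f, " failed: ",
                                          attr(r, "condition")$message)
    else out[[f]] <- r
  }
  out
}

#' Select the best-fitting trajectory family
#'
#' Minimal-SSE selection among converged candidate fits; exact ties go to
#' the family with fewer parameters, then to the fixed order exponential,
#' logistic, log-logistic, Gompertz.
#'
#' @param fits A list of [fit_curve()] results.
#' @return The winning `curve_fit`.
#' @export
select_curve <- function(fits) {
  stopifnot(length(fits) >= 1)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stop("no converged curve fits to select from")
  ord <- order(vapply(fits, `[[`, numeric(1), "sse"),
               curve_npar[vapply(fits, `[[`, character(1), "family")],
               match(vapply(fits, `[[`, character(1), "family"),
                     curve_families))
  fits[[ord[1]]]
}

#' Extrapolate a fitted trajectory
#'
#' Curve values at the requested weeks, clamped to the feasible count range
#' `[0, 28]` and held constant at the horizon value (default week 104, two
#' years) beyond the horizon.
#'
#' @param fit A `curve_fit`.
#' @param weeks Non-negative weeks (may extend past the horizon).
#' @param horizon_weeks Override of the fit's plateau horizon.
#' @return A data.frame with columns `week` and `mean`.
#' @export
extrapolate <- function(fit, weeks, horizon_weeks = fit$horizon_weeks) {
  stopifnot(inherits(fit, "curve_fit"), all(weeks >= 0))
  t_eff <- pmin(weeks, horizon_weeks)
  m <- curve_eval(fit$family, as.list(fit$par), t_eff)
  data.frame(week = weeks, mean = pmin(pmax(m, 0), 28))
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("%s trajectory fit: SSE %.4g, converged %s\n",
              x$family, x$sse, x$converged))
  print(round(x$par, 5))
  invisible(x)
}
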