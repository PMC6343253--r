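new_x <- function(fit, arm, visit_week) {
  if (!visit_week %in% fit$weeks)
    stop("visit week ", visit_week, " is not in the fitted schedule (",
         paste(fit$weeks, collapse = ","), ")")
  if (!arm %in% c(0, 1)) stop("arm must be 0 (placebo) or 1 (active)")
  nm <- names(coef(fit))
  x <- stats::setNames(numeric(length(nm)), nm)
  x["(Intercept)"] <- 1
  wk <- paste0("week", visit_week)
  if (wk %in% nm) x[wk] <- 1
  if ("treatment" %in% nm) x["treatment"] <- arm
  x
}

#' Delta-method predicted mean for an arm and visit
#'
#' Predicted mean count on the response scale (inverse link of the linear
#' predictor; for the zero-inflated family the marginal mean
#' `(1 - pi) exp(eta)`, for random-intercept log-link fits the marginal mean
#' `exp(eta + sigma^2/2)`), with a 95\% Wald interval obtained by first-order
#' propagation of the full parameter covariance through the response-scale
#' gradient (`g' V g`). Intervals are reported unclamped.
#'
#' @param fit An `mmd_fit`.
#' @param arm 0 (placebo) or 1 (active).
#' @param visit_week A week in the fitted schedule.
#' @param vcov_type Covariance used (see [vcov.mmd_fit()]).
#' @return An object of class `predicted_mean` (a one-row data.frame with
#'   `arm`, `visit_week`, `mean`, `se`, `lower`, `upper`).
#' @export
predict_mean <- function(fit, arm, visit_week, vcov_type = "active") {
  stopifnot(inherits(fit, "mmd_fit"))
  x <- new_x(fit, arm, visit_week)
  theta_names <- names(fit$theta)
  V <- if (fit$spec$random_intercept) {
    if (identical(vcov_type, "cluster-robust") ||
        (identical(vcov_type, "active") && !is.null(fit$vcov_cluster_full_re)))
      fit$vcov_cluster_full_re else fit$vcov_model_full_re
  } else vcov(fit, type = vcov_type, full = TRUE)
  g <- stats::setNames(numeric(nrow(V)), rownames(V))
  eta <- sum(x * coef(fit))
  if (fit$spec$link == "log") {
    lam <- exp(eta)
    if (fit$family == "zinb") {
      pi0 <- fit$aux$pi_zero
      m <- (1 - pi0) * lam
      g[names(x)] <- m * x
      g["logit(pi)"] <- -lam * pi0 * (1 - pi0)
    } else if (fit$spec$random_intercept) {
      s <- fit$aux$sigma_re
      m <- exp(eta + s^2 / 2)
      g[names(x)] <- m * x
      g["log(sigma)"] <- m * s^2
    } else {
      m <- lam
      g[names(x)] <- m * x
    }
  } else {
    p <- stats::plogis(eta)
    m <- fit$n_days * p
    g[names(x)] <- fit$n_days * p * (1 - p) * x
  }
  v <- drop(t(g) %*% V %*% g)
  se <- sqrt(max(v, 0))
  structure(data.frame(arm = arm, visit_week = visit_week, mean = m, se = se,
                       lower = m - 1.96 * se, upper = m + 1.96 * se),
            class = c("predicted_mean", "data.frame"))
}

#' Reconstruct the full 0..28 count distribution for an arm and visit
#'
#' Maps the fitted cohort parameters back to a patient-level frequency
#' distribution: negative-binomial and Poisson fits are renormalised onto
#' `0..n_days` by dividing by the unbounded CDF at the bound
#' (see [truncated_pmf()]); the beta-binomial uses its exact bounded mass at
#' the predicted mean and fitted ICC; the zero-inflated negative binomial is
#' mixed first and then renormalised.
#'
#' @inheritParams predict_mean
#' @return An object of class `predicted_distribution` (also a
#'   `truncated_pmf`) with fields `arm`, `visit_week`, `family`, `k`, `prob`,
#'   `norm_const`.
#' @export
predict_distribution <- function(fit, arm, visit_week) {
  stopifnot(inherits(fit, "mmd_fit"))
  if (fit$spec$random_intercept)
    stop("distribution reconstruction is defined for fixed-effects fits")
  eta <- sum(new_x(fit, arm, visit_week) * coef(fit))
  N <- fit$n_days
  params <- switch(fit$family,
    poisson = pois_params(exp(eta)),
    negbin = nb_params(exp(eta), tau = fit$aux$tau),
    zinb = zinb_params(exp(eta), tau = fit$aux$tau, pi_zero = fit$aux$pi_zero),
    betabin = mean_icc_to_shapes(N * stats::plogis(eta), fit$aux$rho, N))
  tp <- truncated_pmf(params, n_max = N)
  structure(c(list(arm = arm, visit_week = visit_week), unclass(tp)),
            class = c("predicted_distribution", "truncated_pmf"))
}

#' Empirical count histogram for an arm and visit
#'
#' Relative frequencies of the observed counts over the full support
#' `0..n_days`, zero-filled.
#'
#' @param data An [mmd_dataset()].
#' @param arm,visit_week Cell selectors.
#' @return An object of class `observed_histogram` with fields `arm`,
#'   `visit_week`, `k`, `prob`, `n_obs`.
#' @export
observed_histogram <- function(data, arm, visit_week) {
  if (!inherits(data, "mmd_dataset")) data <- mmd_dataset(data)
  N <- attr(data, "n_days")
  k <- data$mmd[data$arm == arm & data$visit_week == visit_week]
  if (!length(k))
    stop(sprintf("no observations in cell arm=%d, week=%d", arm, visit_week))
  tab <- tabulate(k + 1L, nbins = N + 1L)
  structure(list(arm = arm, visit_week = visit_week, k = 0:N,
                 prob = tab / sum(tab), n_obs = length(k)),
            class = "observed_histogram")
}

gof_cells <- function(data) {
  cells <- unique(as.data.frame(data)[, c("arm", "visit_week")])
  cells[order(cells$arm, cells$visit_week), , drop = FALSE]
}

#' Goodness of fit of reconstructed distributions and predicted means
#'
#' RMSE and MAE are reported under both natural conventions, since either may
#' be meant by "error across estimated values versus observations":
#' `bin-level` pools the per-bin differences between the predicted and the
#' observed relative frequencies over every arm-by-visit cell (29 bins per
#' cell); `visit-mean-level` uses the differences between the predicted and
#' the observed mean count of each cell. On any one error vector
#' RMSE >= MAE.
#'
#' @param fit A converged `mmd_fit`.
#' @param data The [mmd_dataset()] the fit is compared against.
#' @return An object of class `gof_report`: per-convention lists with
#'   `rmse`, `mae` and the raw `errors` vector.
#' @export
goodness_of_fit <- function(fit, data) {
  stopifnot(inherits(fit, "mmd_fit"))
  if (!inherits(data, "mmd_dataset")) data <- mmd_dataset(data, fit$n_days)
  cells <- gof_cells(data)
  cells <- cells[cells$visit_week %in% fit$weeks, , drop = FALSE]
  if (!nrow(cells)) stop("no arm-by-visit cells match the fitted schedule")
  bin_err <- numeric(0)
  mean_err <- numeric(0)
  for (i in seq_len(nrow(cells))) {
    a <- cells$arm[i]; w <- cells$visit_week[i]
    pd <- predict_distribution(fit, a, w)
    oh <- observed_histogram(data, a, w)
    bin_err <- c(bin_err, pd$prob - oh$prob)
    obs_mean <- sum(oh$k * oh$prob)
    mean_err <- c(mean_err, predict_mean(fit, a, w)$mean - obs_mean)
  }
  mk <- function(e) list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)), errors = e)
  structure(list(family = fit$family,
                 bin_level = mk(bin_err),
                 visit_mean_level = mk(mean_err),
                 n_cells = nrow(cells)),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("Goodness of fit (%s), %d arm-by-visit cells\n",
              x$family, x$n_cells))
  cat(sprintf("  bin-level:        RMSE %.4f  MAE %.4f\n",
              x$bin_level$rmse, x$bin_level$mae))
  cat(sprintf("  visit-mean-level: RMSE %.4f  MAE %.4f\n",
              x$visit_mean_level$rmse, x$visit_mean_level$mae))
  invisible(x)
}

#' Predicted vs observed distribution table for all cells
#'
#' @param fit An `mmd_fit`.
#' @param data An [mmd_dataset()].
#' @return A data.frame with columns `arm`, `visit_week`, `k`,
#'   `predicted_prob`, `observed_prob`.
#' @export
distributions_table <- function(fit, data) {
  if (!inherits(data, "mmd_dataset")) data <- mmd_dataset(data, fit$n_days)
  cells <- gof_cells(data)
  cells <- cells[cells$visit_week %in% fit$weeks, , drop = FALSE]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    a <- cells$arm[i]; w <- cells$visit_week[i]
    pd <- predict_distribution(fit, a, w)
    oh <- observed_histogram(data, a, w)
    data.frame(arm = a, visit_week = w, k = pd$k,
               predicted_prob = pd$prob, observed_prob = oh$prob)
  })
  do.call(rbind, out)
}

#' Predicted mean trajectory table
#'
#' Per-visit delta-method predicted means and intervals for one or both arms,
#' in ascending week order; the natural input for [fit_curve()].
#'
#' @param fit An `mmd_fit`.
#' @param arms Arms to include (default both).
#' @return A data.frame `arm`, `visit_week`, `mean`, `se`, `lower`, `upper`.
#' @export
predicted_trajectory <- function(fit, arms = c(0, 1)) {
  out <- lapply(arms, function(a)
    do.call(rbind, lapply(fit$weeks, function(w)
      as.data.frame(predict_mean(fit, a, w)))))
  do.call(rbind, out)
}
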