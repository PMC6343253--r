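#' Parameter-recovery (estimator calibration) experiment
#'
#' Repeatedly simulates a trial from the exact generative model of
#' [recovery_config()] — the published study design with the published
#' fitted trajectory, treatment effect and dispersion/ICC as truth — refits
#' the corresponding regression, and collects the quantities of interest per
#' seed: the auxiliary parameter (dispersion in the reporting convention, or
#' ICC), the week-0 placebo delta-method predicted mean, and the treatment
#' effect (FRR for log-link families, coefficient for the beta-binomial).
#'
#' @param cohort `"EM"` or `"CM"`.
#' @param family `"negbin"`, `"betabin"`, `"poisson"` or `"zinb"`.
#' @param n_seeds Number of replicate trials (default 20).
#' @param base_seed Integer; replicate `i` uses seed `base_seed + i - 1`.
#' @return An object of class `recovery_experiment`: a data.frame with one
#'   row per seed (columns `seed`, `aux`, `week0_mean`, `treatment_effect`,
#'   `converged`) carrying the generative-truth values and the problem size
#'   as attributes `truth` and `n_obs`.
#' @examples
#' \donttest{
#' rec <- recovery_experiment("CM", "negbin", n_seeds = 3, base_seed = 1)
#' colMeans(rec[, c("aux", "week0_mean", "treatment_effect")])
#' attr(rec, "truth")
#' }
#' @export
recovery_experiment <- function(cohort, family, n_seeds = 20L,
                                base_seed = 1L) {
  stopifnot(n_seeds >= 1)
  spec <- regression_spec(family)
  rows <- vector("list", n_seeds)
  n_obs <- NA_integer_
  cfg0 <- recovery_config(cohort, family)
  for (i in seq_len(n_seeds)) {
    cfg <- recovery_config(cohort, family, seed = base_seed + i - 1L)
    fit <- fit_mmd(simulate_trial(cfg), spec)
    n_obs <- fit$n_obs
    aux <- switch(family, negbin = , zinb = fit$aux$alpha_report,
                  betabin = fit$aux$rho, poisson = NA_real_)
    eff <- unname(coef(fit)["treatment"])
    rows[[i]] <- data.frame(
      seed = base_seed + i - 1L, aux = aux,
      week0_mean = predict_mean(fit, 0, 0)$mean,
      treatment_effect = if (spec$link == "log") exp(eff) else eff,
      converged = fit$converged)
  }
  out <- do.call(rbind, rows)
  truth <- c(aux = switch(family, negbin = , zinb = cfg0$alpha_report,
                          betabin = cfg0$rho, poisson = NA_real_),
             week0_mean = cfg0$placebo_means[1],
             treatment_effect = cfg0$treatment_effect)
  structure(out, truth = truth, n_obs = n_obs,
            class = c("recovery_experiment", "data.frame"))
}

#' Summarise a recovery experiment
#'
#' Means, Monte-Carlo standard errors of the means, and the generative truth
#' for each recovered quantity.
#'
#' @param object A [recovery_experiment()] result.
#' @param ... Unused.
#' @return A data.frame with columns `quantity`, `truth`, `mean`, `mc_se`,
#'   `z` (standardised deviation of the mean from truth).
#' @export
summary.recovery_experiment <- function(object, ...) {
  truth <- attr(object, "truth")
  qty <- intersect(names(truth), names(object))
  qty <- qty[!is.na(truth[qty])]
  est <- vapply(qty, function(q) mean(object[[q]]), numeric(1))
  mcse <- vapply(qty, function(q)
    stats::sd(object[[q]]) / sqrt(nrow(object)), numeric(1))
  data.frame(quantity = qty, truth = unname(truth[qty]), mean = unname(est),
             mc_se = unname(mcse), z = unname((est - truth[qty]) / mcse),
             row.names = NULL)
}
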