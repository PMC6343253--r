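#' Specify a longitudinal count regression
#'
#' Fixed covariate structure for all families: an intercept, one indicator
#' per non-reference visit (reference = earliest week), and a treatment
#' indicator; no treatment-by-visit interactions. Count families (Poisson,
#' negative binomial, zero-inflated negative binomial) use a log link on the
#' mean count; the beta-binomial uses a logit link on the mean daily
#' proportion with a constant intraclass correlation (ICC) over time. The
#' dispersion (negative binomial), ICC (beta-binomial) and zero-inflation
#' probability are each held constant over visits.
#'
#' @param family One of `"poisson"`, `"negbin"`, `"betabin"`, `"zinb"`.
#' @param variance_mode `"cluster-robust"` (sandwich covariance clustered on
#'   subject; the default) or `"model-based"` (inverse observed information).
#' @param random_intercept Add a normal random intercept on the link scale,
#'   integrated by adaptive Gauss-Hermite quadrature (Poisson and negative
#'   binomial only).
#' @param quadrature_nodes Number of Gauss-Hermite nodes (default 15).
#' @param n_days Period length bounding the counts (default 28).
#' @param sigma_fixed Optional fixed value for the random-intercept SD
#'   (e.g. 0 to recover the fixed-effects fit through the quadrature path);
#'   `NULL` (default) estimates it.
#' @param covariates `"visit_treatment"` (the default full design) or
#'   `"intercept"` (a single overall mean, e.g. for calibration checks).
#' @return An object of class `regression_spec`.
#' @export
regression_spec <- function(family = c("negbin", "betabin", "poisson", "zinb"),
                            variance_mode = c("cluster-robust", "model-based"),
                            random_intercept = FALSE,
                            quadrature_nodes = 15L,
                            n_days = 28L,
                            sigma_fixed = NULL,
                            covariates = c("visit_treatment", "intercept")) {
  family <- match.arg(family)
  variance_mode <- match.arg(variance_mode)
  covariates <- match.arg(covariates)
  if (random_intercept && !family %in% c("poisson", "negbin"))
    stop("random intercepts are supported for the poisson and negbin families only")
  stopifnot(quadrature_nodes >= 3, n_days >= 1)
  structure(list(family = family,
                 link = if (family == "betabin") "logit" else "log",
                 variance_mode = variance_mode,
                 random_intercept = isTRUE(random_intercept),
                 quadrature_nodes = as.integer(quadrature_nodes),
                 n_days = as.integer(n_days),
                 sigma_fixed = sigma_fixed,
                 covariates = covariates),
            class = "regression_spec")
}

#' Build the design matrix for a trial dataset
#'
#' One row per observation; columns are the intercept, an indicator per
#' non-reference visit (ascending week order) and the treatment indicator.
#' A non-reference visit with an empty visit-by-arm cell has its indicator
#' dropped with a warning.
#'
#' @param data An [mmd_dataset()] (or conforming data.frame).
#' @param spec A [regression_spec()].
#' @return A list with the design matrix `X`, response `y`, `cluster`
#'   (subject ids), `weeks` (modelled visit weeks), `ref_week`, and `n_days`.
#' @export
build_design <- function(data, spec = regression_spec()) {
  if (!inherits(data, "mmd_dataset")) data <- mmd_dataset(data, spec$n_days)
  weeks <- sort(unique(data$visit_week))
  if (identical(spec$covariates, "intercept")) {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
    return(list(X = X, y = as.numeric(data$mmd), cluster = data$subject_id,
                weeks = weeks, ref_week = weeks[1],
                n_days = attr(data, "n_days") %||% spec$n_days))
  }
  if (length(weeks) < 2L)
    stop("at least two distinct visits are required for visit indicators")
  ref <- weeks[1]
  keep <- weeks[-1]
  cells <- table(factor(data$visit_week, levels = weeks), factor(data$arm, levels = 0:1))
  empty <- keep[apply(cells[as.character(keep), , drop = FALSE] == 0, 1, any)]
  if (length(empty)) {
    warning("dropping visit indicator(s) with an empty visit-by-arm cell: week ",
            paste(empty, collapse = ", "))
    keep <- setdiff(keep, empty)
  }
  X <- cbind(1,
             vapply(keep, function(w) as.numeric(data$visit_week == w),
                    numeric(nrow(data))),
             as.numeric(data$arm))
  colnames(X) <- c("(Intercept)", paste0("week", keep), "treatment")
  list(X = X, y = as.numeric(data$mmd), cluster = data$subject_id,
       weeks = c(ref, keep), ref_week = ref, n_days = attr(data, "n_days") %||% spec$n_days)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- per-observation log-likelihoods and scores (theta = c(beta, aux)) ----

theta_split <- function(theta, p, family) {
  theta <- unname(theta)
  out <- list(beta = theta[seq_len(p)])
  if (family == "negbin") out$tau <- exp(theta[p + 1])
  if (family == "betabin") out$rho <- stats::plogis(theta[p + 1])
  if (family == "zinb") {
    out$tau <- exp(theta[p + 1]); out$pi <- stats::plogis(theta[p + 2])
  }
  out
}

n_aux <- function(family) switch(family, poisson = 0L, negbin = 1L,
                                 betabin = 1L, zinb = 2L)

ll_rows <- function(theta, X, y, family, n_days) {
  p <- ncol(X); pa <- theta_split(theta, p, family)
  eta <- drop(X %*% pa$beta)
  if (family == "poisson") {
    stats::dpois(y, exp(eta), log = TRUE)
  } else if (family == "negbin") {
    lam <- exp(eta); tau <- pa$tau
    lgamma(y + tau) - lgamma(tau) - lgamma(y + 1) +
      tau * (log(tau) - log(tau + lam)) + y * (eta - log(lam + tau))
  } else if (family == "betabin") {
    pr <- stats::plogis(eta); th <- (1 - pa$rho) / pa$rho
    a <- pr * th; b <- (1 - pr) * th; N <- n_days
    lchoose(N, y) + lbeta(a + y, b + N - y) - lbeta(a, b)
  } else {
    lam <- exp(eta); tau <- pa$tau; pi0 <- pa$pi
    nbll <- lgamma(y + tau) - lgamma(tau) - lgamma(y + 1) +
      tau * (log(tau) - log(tau + lam)) + y * (eta - log(lam + tau))
    out <- log1p(-pi0) + nbll
    z <- y == 0
    if (any(z)) {
      a1 <- log(pi0); a2 <- log1p(-pi0) + nbll[z]
      m <- pmax(a1, a2)
      out[z] <- m + log(exp(a1 - m) + exp(a2 - m))
    }
    out
  }
}

# n x length(theta) matrix of per-observation score contributions
score_rows <- function(theta, X, y, family, n_days) {
  p <- ncol(X); pa <- theta_split(theta, p, family)
  eta <- drop(X %*% pa$beta)
  if (family == "poisson") {
    return(X * (y - exp(eta)))
  }
  if (family == "negbin") {
    lam <- exp(eta); tau <- pa$tau
    se <- y - (y + tau) * lam / (lam + tau)
    st <- tau * (digamma(y + tau) - digamma(tau) + log(tau / (tau + lam)) +
                   (lam - y) / (tau + lam))
    return(cbind(X * se, st))
  }
  if (family == "betabin") {
    pr <- stats::plogis(eta); th <- (1 - pa$rho) / pa$rho
    a <- pr * th; b <- (1 - pr) * th; N <- n_days
    co <- digamma(a + b) - digamma(a + b + N)
    da <- digamma(a + y) - digamma(a) + co
    db <- digamma(b + N - y) - digamma(b) + co
    se <- (da - db) * th * pr * (1 - pr)
    sr <- -th * (pr * da + (1 - pr) * db)
    return(cbind(X * se, sr))
  }
  # zinb: central finite differences of the per-row log-likelihood
  q <- length(theta)
  S <- matrix(0, length(y), q)
  h <- pmax(1e-6, 1e-6 * abs(theta))
  for (j in seq_len(q)) {
    tp <- tm <- theta; tp[j] <- tp[j] + h[j]; tm[j] <- tm[j] - h[j]
    S[, j] <- (ll_rows(tp, X, y, family, n_days) -
                 ll_rows(tm, X, y, family, n_days)) / (2 * h[j])
  }
  S
}

## ---- starting values -------------------------------------------------------

start_values <- function(X, y, family, n_days) {
  p <- ncol(X)
  if (family == "betabin") {
    g <- suppressWarnings(
      stats::glm.fit(X, y / n_days, weights = rep(n_days, length(y)),
                     family = stats::binomial()))
    beta0 <- g$coefficients
    pr <- stats::plogis(drop(X %*% beta0))
    phi <- sum((y - n_days * pr)^2 / (n_days * pr * (1 - pr))) / (length(y) - p)
    rho0 <- min(max((phi - 1) / (n_days - 1), 1e-3), 0.6)
    return(c(beta0, stats::qlogis(rho0)))
  }
  g <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  beta0 <- g$coefficients
  mu <- exp(drop(X %*% beta0))
  if (family == "poisson") return(beta0)
  alpha0 <- min(max(sum((y - mu)^2 - mu) / sum(mu^2), 1e-3), 50)
  if (family == "negbin") return(c(beta0, -log(alpha0)))
  c(beta0, -log(alpha0), stats::qlogis(0.05))
}

## ---- fitting ---------------------------------------------------------------

#' Fit a longitudinal count regression by maximum likelihood
#'
#' Maximises the analytic log-likelihood of the chosen family over the
#' regression coefficients and the transformed auxiliary parameter
#' (log dispersion, logit ICC, logit inflation) by L-BFGS-B from moment-based
#' starting values, followed by Newton polishing of the gradient. Covariance
#' is the inverse observed information, plus a subject-clustered sandwich
#' when `variance_mode = "cluster-robust"`. With
#' `spec$random_intercept = TRUE` a normal intercept on the link scale is
#' integrated out by adaptive Gauss-Hermite quadrature.
#'
#' @param data An [mmd_dataset()] (or conforming data.frame).
#' @param spec A [regression_spec()].
#' @param start Optional starting vector on the transformed scale
#'   `c(beta, aux)`.
#' @return An object of class `mmd_fit`; see [coef.mmd_fit()],
#'   [vcov.mmd_fit()], [frequency_rate_ratios()], [predict_mean()],
#'   [predict_distribution()].
#' @examples
#' \donttest{
#' sim <- simulate_trial(recovery_config("EM", "negbin", seed = 1))
#' fit <- fit_mmd(sim, regression_spec("negbin"))
#' fit$aux$alpha_report
#' }
#' @export
fit_mmd <- function(data, spec = regression_spec(), start = NULL) {
  if (!inherits(data, "mmd_dataset")) data <- mmd_dataset(data, spec$n_days)
  des <- build_design(data, spec)
  if (spec$random_intercept)
    return(fit_mmd_ranef(data, spec, des, start))
  X <- des$X; y <- des$y; p <- ncol(X); fam <- spec$family
  if (fam %in% c("negbin", "betabin") && all(y == 0))
    stop("all-zero response: ", fam, " auxiliary parameter is not identified")
  q <- p + n_aux(fam)
  if (is.null(start)) start <- start_values(X, y, fam, spec$n_days)
  stopifnot(length(start) == q)
  negll <- function(th) {
    v <- -sum(ll_rows(th, X, y, fam, spec$n_days))
    if (!is.finite(v)) .Machine$double.xmax / 1e6 else v
  }
  neggr <- function(th) -colSums(score_rows(th, X, y, fam, spec$n_days))
  lower <- c(rep(-Inf, p), rep(-16, q - p))
  upper <- c(rep(Inf, p), rep(16, q - p))
  opt <- stats::optim(start, negll, neggr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e1, pgtol = 1e-10))
  theta <- opt$par
  # Newton polish toward a small gradient norm (skipped at the aux bounds)
  at_bound <- any(theta <= lower + 1e-8) || any(theta >= upper - 1e-8)
  if (!at_bound) {
    for (it in 1:10) {
      g <- neggr(theta)
      if (max(abs(g)) < 1e-8) break
      H <- try(stats::optimHess(theta, negll, neggr), silent = TRUE)
      step <- try(solve(H, g), silent = TRUE)
      if (inherits(step, "try-error")) break
      cand <- theta - step
      if (any(cand < lower) || any(cand > upper) || negll(cand) > negll(theta) + 1e-9)
        break
      theta <- cand
    }
  }
  g_final <- neggr(theta)
  ll <- -negll(theta)
  # convergence is judged by the score itself (a flat boundary direction can
  # make the line search exit abnormally while the optimum is found)
  converged <- at_bound || max(abs(g_final)) < 1e-4 * max(1, abs(ll))
  if (!converged)
    warning("fit did not converge (optim code ", opt$convergence,
            ", max |score| ", format(max(abs(g_final)), digits = 3), ")")
  H <- stats::optimHess(theta, negll, neggr)
  vc_model <- solve_psd(H)
  vc_cluster <- NULL
  if (spec$variance_mode == "cluster-robust") {
    S <- score_rows(theta, X, y, fam, spec$n_days)
    Sg <- rowsum(S, des$cluster)
    G <- nrow(Sg)
    meat <- crossprod(Sg) * G / (G - 1)
    vc_cluster <- vc_model %*% meat %*% vc_model
  }
  finish_fit(theta, vc_model, vc_cluster, ll, opt$counts[["function"]],
             converged, des, spec)
}

solve_psd <- function(H) {
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error")) {
    ev <- eigen(H, symmetric = TRUE)
    val <- pmax(ev$values, 1e-10 * max(ev$values))
    V <- ev$vectors %*% diag(1 / val, length(val)) %*% t(ev$vectors)
  }
  (V + t(V)) / 2
}

finish_fit <- function(theta, vc_model, vc_cluster, ll, iters, converged,
                       des, spec, sigma_re = NULL, sigma_idx = NULL) {
  p <- ncol(des$X); fam <- spec$family
  pa <- theta_split(theta, p, fam)
  beta <- stats::setNames(pa$beta, colnames(des$X))
  nm <- colnames(des$X)
  if (fam == "negbin") nm <- c(nm, "log(tau)")
  if (fam == "betabin") nm <- c(nm, "logit(rho)")
  if (fam == "zinb") nm <- c(nm, "log(tau)", "logit(pi)")
  if (!is.null(sigma_idx)) nm <- c(nm, "log(sigma)")
  dimnames(vc_model) <- list(nm, nm)
  if (!is.null(vc_cluster)) dimnames(vc_cluster) <- list(nm, nm)
  aux <- list()
  if (!is.null(pa$tau)) {
    aux$tau <- pa$tau; aux$alpha_report <- 1 / pa$tau
    j <- p + 1
    aux$alpha_report_se <- aux$alpha_report * sqrt(vc_model[j, j])
  }
  if (!is.null(pa$rho)) {
    aux$rho <- pa$rho
    j <- p + 1
    aux$rho_se <- pa$rho * (1 - pa$rho) * sqrt(vc_model[j, j])
  }
  if (!is.null(pa$pi)) aux$pi_zero <- pa$pi
  if (!is.null(sigma_re)) aux$sigma_re <- sigma_re
  structure(list(family = fam, spec = spec, coefficients = beta,
                 theta = stats::setNames(theta, nm),
                 vcov_model = vc_model, vcov_cluster = vc_cluster,
                 aux = aux, loglik = ll, iterations = iters,
                 converged = converged,
                 n_obs = length(des$y),
                 n_subjects = length(unique(des$cluster)),
                 weeks = des$weeks, ref_week = des$ref_week,
                 n_days = des$n_days),
            class = "mmd_fit")
}

#' Log-likelihood of a fitted or hypothesised parameter set
#'
#' Evaluates the exact model log-likelihood of a dataset at arbitrary
#' coefficient and auxiliary values, on the natural scale. This is the same
#' function maximised by [fit_mmd()] and is exposed so that fitted likelihoods
#' can be compared against generative-truth likelihoods.
#'
#' @param data An [mmd_dataset()].
#' @param spec A [regression_spec()] (fixed-effects families).
#' @param coef Named or positional coefficient vector matching
#'   [build_design()] column order.
#' @param dispersion Negative-binomial dispersion in the reporting
#'   convention (`1/tau`); required for `negbin`/`zinb`.
#' @param rho Beta-binomial ICC; required for `betabin`.
#' @param pi_zero Zero-inflation probability; required for `zinb`.
#' @param by_row If `TRUE`, return the per-observation vector instead of the
#'   sum.
#' @return The summed (or per-row) log-likelihood.
#' @export
mmd_loglik <- function(data, spec, coef, dispersion = NULL, rho = NULL,
                       pi_zero = NULL, by_row = FALSE) {
  if (!inherits(data, "mmd_dataset")) data <- mmd_dataset(data, spec$n_days)
  des <- build_design(data, spec)
  p <- ncol(des$X)
  stopifnot(length(coef) == p)
  aux <- switch(spec$family,
                poisson = numeric(0),
                negbin = { stopifnot(!is.null(dispersion)); -log(dispersion) },
                betabin = { stopifnot(!is.null(rho)); stats::qlogis(rho) },
                zinb = { stopifnot(!is.null(dispersion), !is.null(pi_zero))
                  c(-log(dispersion), stats::qlogis(pi_zero)) })
  r <- ll_rows(c(unname(coef), aux), des$X, des$y, spec$family, spec$n_days)
  if (by_row) r else sum(r)
}

#' @export
coef.mmd_fit <- function(object, ...) object$coefficients

#' Covariance of a fit
#'
#' @param object An `mmd_fit`.
#' @param type `"active"` (the spec's `variance_mode`), `"model-based"` or
#'   `"cluster-robust"`.
#' @param full If `TRUE`, the covariance over coefficients and transformed
#'   auxiliary parameters; otherwise the coefficient block.
#' @param ... Unused.
#' @export
vcov.mmd_fit <- function(object, type = c("active", "model-based",
                                          "cluster-robust"),
                         full = FALSE, ...) {
  type <- match.arg(type)
  if (type == "active")
    type <- if (!is.null(object$vcov_cluster)) "cluster-robust" else "model-based"
  V <- if (type == "cluster-robust") {
    if (is.null(object$vcov_cluster))
      stop("no cluster-robust covariance was computed for this fit")
    object$vcov_cluster
  } else object$vcov_model
  if (full) V else V[seq_along(object$coefficients), seq_along(object$coefficients),
                     drop = FALSE]
}

#' @export
logLik.mmd_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' Frequency rate ratios (or coefficients) with 95\% Wald intervals
#'
#' For log-link families each coefficient is exponentiated into a frequency
#' rate ratio (FRR), the multiplicative effect on the expected count, with
#' `exp(b +/- 1.96 se)` intervals. For the logit-link beta-binomial the
#' coefficients are reported on their own scale (labelled `"coefficient"`),
#' matching how such models are conventionally tabulated.
#'
#' @param fit An `mmd_fit`.
#' @param vcov_type Covariance used for the intervals (see [vcov.mmd_fit()]).
#' @return A data.frame with columns `term`, `scale`, `estimate`, `lower`,
#'   `upper`, `p_value`.
#' @export
frequency_rate_ratios <- function(fit, vcov_type = "active") {
  stopifnot(inherits(fit, "mmd_fit"))
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit, type = vcov_type)))
  z <- b / se
  pval <- 2 * stats::pnorm(-abs(z))
  if (fit$spec$link == "log") {
    data.frame(term = names(b), scale = "FRR",
               estimate = exp(b), lower = exp(b - 1.96 * se),
               upper = exp(b + 1.96 * se), p_value = pval,
               row.names = NULL)
  } else {
    data.frame(term = names(b), scale = "coefficient",
               estimate = b, lower = b - 1.96 * se, upper = b + 1.96 * se,
               p_value = pval, row.names = NULL)
  }
}

#' @export
print.mmd_fit <- function(x, ...) {
  cat(sprintf("Longitudinal %s regression (%s link)\n", x$family, x$spec$link))
  cat(sprintf("  %d observations, %d subjects, visits: weeks %s (ref %d)\n",
              x$n_obs, x$n_subjects, paste(x$weeks, collapse = ","), x$ref_week))
  cat(sprintf("  log-likelihood %.3f, converged: %s\n", x$loglik, x$converged))
  if (!is.null(x$aux$alpha_report))
    cat(sprintf("  dispersion (reporting convention) %.4f\n", x$aux$alpha_report))
  if (!is.null(x$aux$rho)) cat(sprintf("  ICC %.4f\n", x$aux$rho))
  if (!is.null(x$aux$pi_zero))
    cat(sprintf("  zero inflation %.4f\n", x$aux$pi_zero))
  if (!is.null(x$aux$sigma_re))
    cat(sprintf("  random-intercept SD %.4f\n", x$aux$sigma_re))
  print(frequency_rate_ratios(x), digits = 4)
  invisible(x)
}
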