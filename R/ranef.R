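# Adaptive Gauss-Hermite integration of a normal random intercept on the log
# link, for the poisson and negbin families. The integrand is log-concave in
# the intercept for both families, so per-subject modes are found by damped
# Newton iterations run simultaneously over all subjects.

# Nodes/weights for integral f(x) e^{-x^2} dx (Golub-Welsch on the Jacobi
# matrix of the Hermite recurrence).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J <- J + t(J)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Conditional per-row log-likelihood, score d/deta and curvature factor for
# log-link families given the linear predictor eta.
cond_fns <- function(family, tau = NULL) {
  if (family == "poisson") {
    list(ll = function(eta, y) stats::dpois(y, exp(eta), log = TRUE),
         u = function(eta, y) y - exp(eta),
         w = function(eta, y) exp(eta))
  } else {
    list(ll = function(eta, y) {
      lam <- exp(eta)
      lgamma(y + tau) - lgamma(tau) - lgamma(y + 1) +
        tau * (log(tau) - log(tau + lam)) + y * (eta - log(lam + tau))
    },
    u = function(eta, y) {
      lam <- exp(eta); y - (y + tau) * lam / (lam + tau)
    },
    w = function(eta, y) {
      lam <- exp(eta); lam * tau * (y + tau) / (lam + tau)^2
    })
  }
}

# Per-subject marginal log-likelihood vector by adaptive Gauss-Hermite.
agh_loglik_subjects <- function(theta, X, y, gi, G, family, gh) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  tau <- if (family == "negbin") exp(theta[p + 1]) else NULL
  sigma <- exp(theta[length(theta)])
  fns <- cond_fns(family, tau)
  eta0 <- drop(X %*% beta)
  # damped Newton for the per-subject mode of h(z) = sum ll + log phi(z)
  z <- numeric(G)
  for (it in 1:40) {
    eta <- eta0 + sigma * z[gi]
    g1 <- sigma * rowsum_vec(fns$u(eta, y), gi, G) - z
    g2 <- -sigma^2 * rowsum_vec(fns$w(eta, y), gi, G) - 1
    step <- g1 / g2
    step <- pmax(pmin(step, 2), -2)
    z <- z - step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- eta0 + sigma * z[gi]
  s <- 1 / sqrt(sigma^2 * rowsum_vec(fns$w(eta, y), gi, G) + 1)
  Q <- length(gh$nodes)
  hq <- matrix(0, G, Q)
  for (q in seq_len(Q)) {
    zq <- z + sqrt(2) * s * gh$nodes[q]
    hq[, q] <- rowsum_vec(fns$ll(eta0 + sigma * zq[gi], y), gi, G) -
      zq^2 / 2 + gh$nodes[q]^2 + log(gh$weights[q])
  }
  m <- apply(hq, 1, max)
  m + log(rowSums(exp(hq - m))) + log(sqrt(2) * s) - 0.5 * log(2 * pi)
}

rowsum_vec <- function(x, gi, G) {
  out <- numeric(G)
  tmp <- rowsum(x, gi)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

fit_mmd_ranef <- function(data, spec, des, start = NULL) {
  X <- des$X; y <- des$y; p <- ncol(X); fam <- spec$family
  gi <- as.integer(factor(des$cluster))
  G <- max(gi)
  gh <- gauss_hermite(spec$quadrature_nodes)
  sigma_fixed <- spec$sigma_fixed
  if (is.null(start)) {
    fe_spec <- spec; fe_spec$random_intercept <- FALSE
    fe_spec$variance_mode <- "model-based"
    fe <- fit_mmd(data, fe_spec)
    start <- c(unname(fe$theta), log(0.3))
  }
  q <- length(start)
  free <- if (is.null(sigma_fixed)) seq_len(q) else seq_len(q - 1L)
  if (!is.null(sigma_fixed))
    start[q] <- log(max(sigma_fixed, 1e-12))
  negll <- function(th_free) {
    th <- start; th[free] <- th_free
    v <- -sum(agh_loglik_subjects(th, X, y, gi, G, fam, gh))
    if (!is.finite(v)) .Machine$double.xmax / 1e6 else v
  }
  lower <- c(rep(-Inf, p), if (fam == "negbin") -16, -8)[free]
  upper <- c(rep(Inf, p), if (fam == "negbin") 16, 3)[free]
  opt <- stats::optim(start[free], negll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e3))
  theta <- start; theta[free] <- opt$par
  ll <- -negll(opt$par)
  converged <- opt$convergence == 0
  if (!converged)
    warning("random-intercept fit did not converge (optim code ",
            opt$convergence, ")")
  H <- stats::optimHess(opt$par, negll)
  vc_free <- solve_psd(H)
  vc_model <- matrix(0, q, q)
  vc_model[free, free] <- vc_free
  vc_cluster <- NULL
  if (spec$variance_mode == "cluster-robust") {
    # per-subject scores by central differences of the subject log-likelihoods
    S <- matrix(0, G, length(free))
    h <- pmax(1e-5, 1e-5 * abs(opt$par))
    for (j in seq_along(free)) {
      tp <- tm <- theta
      tp[free[j]] <- tp[free[j]] + h[j]; tm[free[j]] <- tm[free[j]] - h[j]
      S[, j] <- (agh_loglik_subjects(tp, X, y, gi, G, fam, gh) -
                   agh_loglik_subjects(tm, X, y, gi, G, fam, gh)) / (2 * h[j])
    }
    meat <- crossprod(S) * G / (G - 1)
    vcl <- vc_free %*% meat %*% vc_free
    vc_cluster <- matrix(0, q, q)
    vc_cluster[free, free] <- vcl
  }
  sigma_re <- exp(theta[q])
  fit <- finish_fit(theta[-q], vc_model[-q, -q, drop = FALSE],
                    if (is.null(vc_cluster)) NULL else
                      vc_cluster[-q, -q, drop = FALSE],
                    ll, opt$counts[["function"]], converged, des, spec,
                    sigma_re = sigma_re)
  # keep the full covariance (including log sigma) for delta-method use
  nm <- c(names(fit$theta), "log(sigma)")
  dimnames(vc_model) <- list(nm, nm)
  fit$vcov_model_full_re <- vc_model
  if (!is.null(vc_cluster)) {
    dimnames(vc_cluster) <- list(nm, nm)
    fit$vcov_cluster_full_re <- vc_cluster
  }
  fit
}
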