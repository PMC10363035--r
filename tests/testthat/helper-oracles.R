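# Independent oracles used across the suite. These deliberately re-derive
# quantities through different code paths than the package implementation.

# Adaptive Gauss-Hermite quadrature for the marginal log-likelihood of the
# biexponential mixed model: per-subject mode and curvature found with
# stats::optim/optimHess on a locally written joint density, remainder
# integrated exactly on a mode-centered, curvature-scaled product grid.
agh_marginal_loglik <- function(tumor, theta, omega2, sigma2, nodes = 25) {
  gq <- statmod::gauss.quad(nodes, "hermite")
  total <- 0
  for (id in unique(tumor$subject_id)) {
    d <- tumor[tumor$subject_id == id, , drop = FALSE]
    kgn <- if (d$arm[1] == "treatment") "kg_treatment" else "kg_control"
    ksn <- sub("kg", "ks", kgn)
    w2 <- c(omega2[[kgn]], omega2[[ksn]], omega2[["ts0"]])
    joint_ll <- function(eta) {
      kg <- theta[[kgn]] * exp(eta[1])
      ks <- theta[[ksn]] * exp(eta[2])
      ts0 <- theta[["ts0"]] * exp(eta[3])
      pred <- ifelse(d$time_weeks < 0,
                     ts0 * exp(kg * d$time_weeks),
                     ts0 * (exp(-ks * d$time_weeks) + exp(kg * d$time_weeks) - 1))
      sum(dnorm(d$sld_mm, pred, sqrt(sigma2), log = TRUE)) +
        sum(dnorm(eta, 0, sqrt(w2), log = TRUE))
    }
    op <- stats::optim(c(0, 0, 0), function(e) -joint_ll(e), method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-14))
    H <- stats::optimHess(op$par, function(e) -joint_ll(e))
    L <- t(chol(solve(H)))
    g <- as.matrix(expand.grid(seq_len(nodes), seq_len(nodes), seq_len(nodes)))
    X <- cbind(gq$nodes[g[, 1]], gq$nodes[g[, 2]], gq$nodes[g[, 3]])
    logw <- log(gq$weights[g[, 1]]) + log(gq$weights[g[, 2]]) +
      log(gq$weights[g[, 3]])
    eta_k <- t(op$par + sqrt(2) * (L %*% t(X)))
    ll_k <- apply(eta_k, 1, joint_ll)
    terms <- ll_k + rowSums(X^2) + logw
    mx <- max(terms)
    total <- total + mx + log(sum(exp(terms - mx))) +
      1.5 * log(2) + sum(log(diag(L)))
  }
  total
}

# Written-out Cox partial log-likelihood for a binary covariate, no ties
# assumed; maximized by golden-section search.
cox_brute_force_hr <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event == 1]))
  pll <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
    s
  }
  exp(stats::optimize(pll, c(-8, 8), maximum = TRUE, tol = 1e-10)$maximum)
}

# Small noisy trajectory set drawn around given typical values.
make_toy_tumor <- function(ids, arms, theta, iiv_sd = 0.2, sigma = 3,
                           times = c(-4, 0, 8, 16, 24, 40), seed = 31) {
  set.seed(seed)
  out <- lapply(seq_along(ids), function(i) {
    kgn <- if (arms[i] == "treatment") "kg_treatment" else "kg_control"
    ksn <- sub("kg", "ks", kgn)
    kg <- theta[[kgn]] * exp(rnorm(1, 0, iiv_sd))
    ks <- theta[[ksn]] * exp(rnorm(1, 0, iiv_sd))
    ts0 <- theta[["ts0"]] * exp(rnorm(1, 0, iiv_sd))
    data.frame(subject_id = ids[i], arm = arms[i], time_weeks = times,
               sld_mm = ts_model(times, ts0, kg, ks) + rnorm(length(times), 0, sigma),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

toy_theta <- c(kg_treatment = 0.002, ks_treatment = 0.035,
               kg_control = 0.004, ks_control = 0.037, ts0 = 55)

# A small complete virtual trial shared by I/O and pipeline tests.
small_trial <- function(seed = 7, n_per_arm = 12, n_baseline_only = 3) {
  generate_trial(generator_config(n_per_arm = n_per_arm,
                                  n_baseline_only = n_baseline_only,
                                  seed = seed))
}
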