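# Full-posterior engine: negative-binomial regression with nested varying
# intercepts sampled in JAGS, using the NB2 parameterization
#   y ~ NegBin(p, theta),  p = theta / (theta + mu)
# so that Var(y) = mu + mu^2/theta. Weakly informative priors:
# Normal(0, 2.5) on standardized-scale coefficients, half-Normal(0, 1) on
# varying-intercept SDs, Gamma(2, 0.1) on theta.

jags_model_string <- function(n_re) {
  re_part <- if (n_re >= 1) " + a1[f1[i]]" else ""
  re_part <- paste0(re_part, if (n_re >= 2) " + a2[f2[i]]" else "")
  re_blocks <- ""
  if (n_re >= 1) {
    re_blocks <- paste0(re_blocks,
      "  for (j in 1:J1) { a1[j] ~ dnorm(0, tau1) }\n",
      "  sd1 ~ dnorm(0, 1) T(0,)\n  tau1 <- pow(sd1, -2)\n")
  }
  if (n_re >= 2) {
    re_blocks <- paste0(re_blocks,
      "  for (j in 1:J2) { a2[j] ~ dnorm(0, tau2) }\n",
      "  sd2 ~ dnorm(0, 1) T(0,)\n  tau2 <- pow(sd2, -2)\n")
  }
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    y[i] ~ dnegbin(p[i], theta)\n",
    "    p[i] <- theta / (theta + mu[i])\n",
    "    log(mu[i]) <- inprod(X[i,], b[])", re_part, "\n",
    "  }\n",
    "  for (p in 1:P) { b[p] ~ dnorm(0, 0.16) }\n",
    re_blocks,
    "  theta ~ dgamma(2, 0.1)\n",
    "}\n")
}

fit_outcome_mcmc <- function(spec, prep, seed, chains, iter, warmup,
                             check_convergence) {
  if (!requireNamespace("rjags", quietly = TRUE) ||
      !requireNamespace("coda", quietly = TRUE)) {
    stop("engine 'mcmc' needs the rjags and coda packages")
  }
  dat <- prep$data
  X <- stats::model.matrix(prep$fixed_formula, dat)
  groups <- spec$grouping
  jd <- list(y = dat$cover, X = X, N = nrow(X), P = ncol(X))
  if (length(groups) >= 1) {
    f1 <- factor(dat[[groups[1]]])
    jd$f1 <- as.integer(f1); jd$J1 <- nlevels(f1)
  }
  if (length(groups) >= 2) {
    f2 <- factor(dat[[groups[2]]])
    jd$f2 <- as.integer(f2); jd$J2 <- nlevels(f2)
  }
  monitors <- c("b", "theta",
                if (length(groups) >= 1) c("sd1", "a1"),
                if (length(groups) >= 2) c("sd2", "a2"))
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = keyed_seed(seed, 7L, ch))
  })
  model <- rjags::jags.model(textConnection(jags_model_string(length(groups))),
                             data = jd, inits = inits, n.chains = chains,
                             n.adapt = min(500L, warmup), quiet = TRUE)
  stats::update(model, n.iter = warmup, progress.bar = "none")
  samp <- rjags::coda.samples(model, variable.names = monitors,
                              n.iter = iter - warmup, progress.bar = "none")

  all_names <- colnames(samp[[1]])
  core <- c(paste0("b[", seq_len(ncol(X)), "]"), "theta",
            if (length(groups) >= 1) "sd1", if (length(groups) >= 2) "sd2")
  core_samp <- samp[, core, drop = FALSE]
  gd <- coda::gelman.diag(core_samp, autoburnin = FALSE, multivariate = FALSE)
  rhat <- gd$psrf[, 1]
  ess <- coda::effectiveSize(core_samp)
  diag_report <- list(engine = "jags", max_rhat = max(rhat), min_ess = min(ess),
                      chains = chains, iter = iter, warmup = warmup)
  if (check_convergence && (max(rhat) >= 1.01 || min(ess) <= 400)) {
    stop(sprintf(paste0("MCMC did not converge: max R-hat %.4f (need < 1.01), ",
                        "min ESS %.0f (need > 400); increase iter/warmup"),
                 max(rhat), min(ess)))
  }

  M <- as.matrix(samp)
  bdraws <- M[, paste0("b[", seq_len(ncol(X)), "]"), drop = FALSE]
  colnames(bdraws) <- colnames(X)
  est <- apply(bdraws, 2, stats::median)
  se <- apply(bdraws, 2, stats::sd)
  ci <- apply(bdraws, 2, stats::quantile, probs = c(0.025, 0.975))
  coefs <- data.frame(term = colnames(X), estimate = unname(est),
                      se = unname(se), lwr = unname(ci[1, ]),
                      upr = unname(ci[2, ]), row.names = NULL)
  theta <- stats::median(M[, "theta"])
  sigma <- numeric(0)
  if (length(groups) >= 1) sigma[groups[1]] <- stats::median(M[, "sd1"])
  if (length(groups) >= 2) sigma[groups[2]] <- stats::median(M[, "sd2"])

  lp <- as.numeric(X %*% est)
  if (length(groups) >= 1) {
    a1 <- apply(M[, paste0("a1[", seq_len(jd$J1), "]"), drop = FALSE], 2, stats::median)
    lp <- lp + a1[jd$f1]
  }
  if (length(groups) >= 2) {
    a2 <- apply(M[, paste0("a2[", seq_len(jd$J2), "]"), drop = FALSE], 2, stats::median)
    lp <- lp + a2[jd$f2]
  }

  structure(list(
    spec = spec, engine = "mcmc", coefficients = coefs,
    beta_term = spec$beta_term, vcov = stats::cov(bdraws), theta = theta,
    sigma = sigma, record = prep$record,
    xlevels = list(ecoregion = if (spec$kind == "covariate") levels(dat$ecoregion),
                   time_f = if (spec$kind == "panel") levels(dat$time_f)),
    fitted = exp(lp), response = dat$cover,
    converged = TRUE, diagnostics = diag_report, seed = as.integer(seed),
    draws = bdraws
  ), class = "outcome_fit")
}
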