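# Diagnostics: parallel pre-trends, binned Moran's I correlogram with a
# permutation null, predictive checks / MAE, and the estimator-comparison
# recovery study.

#' Parallel pre-trends check
#'
#' Compares the pre-period group-mean cover trajectories and tests whether
#' the groups' linear slopes differ. The slope contrast comes from a linear
#' fit of cover on `time x group` over the pre-period rows with
#' heteroskedasticity-consistent (HC3) standard errors; the trajectories are
#' reported alongside, mirroring the visual check.
#'
#' @param sites site table with groups assigned.
#' @param pre_period_observations observation rows from the pre period
#'   (e.g. `time < 0` rows from [simulate_cover_panel()] with `pre_years`).
#' @return list: `trajectory` (per time x group mean, SE, n),
#'   `slope_difference` (estimate, se, lwr, upr), `parallel` (TRUE when the
#'   interval covers 0).
#' @export
parallel_trends_check <- function(sites, pre_period_observations) {
  obs <- merge(pre_period_observations, sites[, c("site_id", "group")],
               by = "site_id")
  if (!nrow(obs)) stop("no pre-period observations")
  tab <- table(obs$group, obs$time)
  if (nrow(tab) < 2) stop("a treatment group is absent from the pre period")
  if (any(rowSums(tab > 0) < 2)) {
    stop("need at least 2 pre-period timepoints per group")
  }
  agg <- stats::aggregate(cover ~ time + group, data = obs, FUN = function(x) {
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
  })
  trajectory <- data.frame(time = agg$time, group = agg$group,
                           mean = agg$cover[, "mean"], se = agg$cover[, "se"],
                           n = agg$cover[, "n"])
  m <- stats::lm(cover ~ time * group, data = obs)
  ct <- lmtest::coeftest(m, vcov. = sandwich::vcovHC(m, type = "HC3"))
  est <- ct["time:group", "Estimate"]
  se <- ct["time:group", "Std. Error"]
  slope <- data.frame(estimate = est, se = se,
                      lwr = est - 1.96 * se, upr = est + 1.96 * se)
  list(trajectory = trajectory[order(trajectory$group, trajectory$time), ],
       slope_difference = slope,
       parallel = slope$lwr <= 0 && slope$upr >= 0)
}

#' Binned Moran's I correlogram with permutation null
#'
#' For each distance bin, Moran's I with row-standardized binary weights
#' (pairs whose distance falls in the bin are neighbours), a permutation
#' p-value (two-sided, against random relabelling of residuals over
#' locations), and the null expectation `-1/(n-1)`.
#'
#' @param residuals numeric vector of model residuals, one per location.
#' @param coords two-column matrix/data.frame of planar coordinates.
#' @param distance_bins increasing numeric break points; bin b is
#'   `(breaks[b], breaks[b+1]]`.
#' @param n_perm number of permutations (default 999).
#' @param seed permutation seed.
#' @return data.frame: bin bounds, pair count, `I`, `expected`, `p_value`
#'   (NA, with `empty = TRUE`, for bins without pairs).
#' @export
morans_i <- function(residuals, coords, distance_bins, n_perm = 999L,
                     seed = 1L) {
  n <- length(residuals)
  if (n < 4) stop("need at least 4 locations")
  if (stats::sd(residuals) == 0) stop("residuals have zero variance")
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n, ncol(coords) == 2)
  D <- as.matrix(stats::dist(coords))
  z <- residuals - mean(residuals)
  denom <- sum(z^2)
  expected <- -1 / (n - 1)

  perms <- with_keyed_seed(seed, 11L, 0L, {
    lapply(seq_len(n_perm), function(i) sample.int(n))
  })

  out <- lapply(seq_len(length(distance_bins) - 1L), function(b) {
    lo <- distance_bins[b]; hi <- distance_bins[b + 1L]
    W <- (D > lo & D <= hi) * 1
    diag(W) <- 0
    rs <- rowSums(W)
    if (all(rs == 0)) {
      return(data.frame(lower = lo, upper = hi, n_pairs = 0L, I = NA_real_,
                        expected = expected, p_value = NA_real_, empty = TRUE))
    }
    n_pairs <- sum(W) / 2
    Wr <- W / ifelse(rs == 0, 1, rs)  # row-standardize; empty rows stay zero
    s0 <- sum(Wr)
    I_of <- function(v) (n / s0) * sum(v * (Wr %*% v)) / denom
    I_obs <- I_of(z)
    I_null <- vapply(perms, function(p) I_of(z[p]), numeric(1))
    # two-sided permutation p with the observed value included in the null set
    p_val <- (1 + sum(abs(I_null - expected) >= abs(I_obs - expected))) /
      (n_perm + 1)
    data.frame(lower = lo, upper = hi, n_pairs = n_pairs, I = I_obs,
               expected = expected, p_value = p_val, empty = FALSE)
  })
  do.call(rbind, out)
}

#' Predictive check and mean absolute error
#'
#' Within-sample MAE (`mean |y - y-hat|` with `y-hat` the fitted expected
#' cover per row, varying intercepts included) plus replicate datasets drawn
#' from the fitted negative binomial, summarizing whether simulated cover
#' exceeds the 100% bound the likelihood ignores.
#'
#' @param fit a converged `outcome_fit`.
#' @param n_draws replicate datasets (default 100).
#' @param seed replicate seed.
#' @return list: `mae`, `observed_mean`, `simulated_mean` (with sd over
#'   replicates), `max_simulated`, `frac_over_100`.
#' @export
predictive_check <- function(fit, n_draws = 100L, seed = 1L) {
  stopifnot(inherits(fit, "outcome_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  mu <- fit$fitted
  y <- fit$response
  mae <- mean(abs(y - mu))
  sims <- with_keyed_seed(seed, 12L, 0L, {
    matrix(stats::rnbinom(n_draws * length(mu), mu = mu, size = fit$theta),
           nrow = n_draws, byrow = TRUE)
  })
  list(mae = mae,
       observed_mean = mean(y),
       simulated_mean = mean(sims),
       simulated_mean_sd = stats::sd(rowMeans(sims)),
       max_simulated = max(sims),
       frac_over_100 = mean(sims > 100))
}

# Fit one estimator on a simulated landscape; returns the treatment
# coefficient row. Matching is run when the estimator needs it.
fit_estimator_once <- function(estimator, frames, sites, engine = "ml",
                               seed = 1L) {
  if (estimator == "matched") {
    pfit <- fit_propensity(sites)
    ms <- match_sites(pfit)
    if (!nrow(ms$pairs)) stop("matching produced no pairs")
    msites <- matched_subset(sites, ms)
    frame <- frames$cross_section[frames$cross_section$site_id %in% msites$site_id, ]
    fit <- fit_outcome(make_spec("matched"), frame, engine = engine, seed = seed)
  } else {
    frame <- frames[[make_spec(estimator)$frame]]
    fit <- fit_outcome(make_spec(estimator), frame, engine = engine, seed = seed)
  }
  treatment_coef(fit)
}

#' Estimator-comparison recovery study
#'
#' Simulates replicate landscapes under a scenario, runs each requested
#' estimator (propensity matching included where needed), and aggregates the
#' treatment coefficient's bias, empirical 95%-interval coverage of the true
#' effect, and sign-error fraction — the quantitative version of the
#' estimator-ladder contrast the package exists to demonstrate.
#'
#' @param scenario preset name or `scenario_config`; replicate r uses the
#'   scenario with seed `seeds[r]`.
#' @param estimators subset of `naive`, `matched`, `covariate`, `did`,
#'   `panel`.
#' @param n_reps number of replicate landscapes (>= 10 for meaningful
#'   coverage; smaller values allowed for smoke use).
#' @param seed base seed; replicate seeds are derived from it (or supply
#'   `seeds` explicitly).
#' @param seeds optional explicit integer vector of length `n_reps`.
#' @param n_fires landscape size per replicate (default 100, the desk-scale
#'   study size).
#' @param engine estimation engine (default `"ml"`, the fast path).
#' @return object of class `recovery_report`: per-estimator summary
#'   (mean bias, coverage, sign-error fraction, failures) and the per-
#'   replicate estimates.
#' @export
recovery_study <- function(scenario, estimators = c("naive", "did", "panel"),
                           n_reps = 30L, seed = 1L, seeds = NULL,
                           n_fires = 100L, engine = "ml") {
  estimators <- match.arg(estimators,
                          c("naive", "matched", "covariate", "did", "panel"),
                          several.ok = TRUE)
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(n_reps), function(r) keyed_seed(seed, 20L, r),
                    integer(1))
  }
  stopifnot(length(seeds) == n_reps)
  scen_name <- if (is.character(scenario)) scenario else "custom"

  rows <- vector("list", n_reps * length(estimators))
  idx <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- if (is.character(scenario)) {
      scenario_preset(scenario, n_fires = n_fires, seed = seeds[r])
    } else {
      cfg_r <- scenario
      cfg_r$seed <- seeds[r]
      cfg_r$n_fires <- as.integer(n_fires)
      cfg_r
    }
    sim <- suppressMessages(simulate_landscape(cfg))
    frames <- suppressMessages(build_frames(sim$sites, sim$observations))
    for (est in estimators) {
      idx <- idx + 1L
      res <- tryCatch(
        suppressMessages(fit_estimator_once(est, frames, sim$sites,
                                            engine = engine, seed = seeds[r])),
        error = function(e) e)
      rows[[idx]] <- if (inherits(res, "error")) {
        data.frame(replicate = r, seed = seeds[r], estimator = est,
                   estimate = NA_real_, se = NA_real_, lwr = NA_real_,
                   upr = NA_real_, failed = TRUE,
                   message = conditionMessage(res))
      } else {
        data.frame(replicate = r, seed = seeds[r], estimator = est,
                   estimate = res$estimate, se = res$se, lwr = res$lwr,
                   upr = res$upr, failed = FALSE, message = "")
      }
    }
  }
  replicates <- do.call(rbind, rows)
  beta_true <- if (is.character(scenario)) {
    scenario_preset(scenario)$true_effect_beta
  } else scenario$true_effect_beta

  summarize <- function(est) {
    d <- replicates[replicates$estimator == est & !replicates$failed, ]
    data.frame(
      estimator = est,
      n_ok = nrow(d),
      n_failed = sum(replicates$estimator == est & replicates$failed),
      mean_estimate = mean(d$estimate),
      mean_bias = mean(d$estimate) - beta_true,
      coverage = mean(d$lwr <= beta_true & d$upr >= beta_true),
      sign_error = if (beta_true == 0) NA_real_ else
        mean(sign(d$estimate) != sign(beta_true)),
      frac_negative = mean(d$estimate < 0)
    )
  }
  summary <- do.call(rbind, lapply(estimators, summarize))
  structure(list(summary = summary, replicates = replicates,
                 scenario = scen_name, beta_true = beta_true,
                 seeds = seeds, n_fires = n_fires, engine = engine),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report: scenario '", x$scenario, "', beta_true = ",
      signif(x$beta_true, 4), ", ", length(x$seeds), " replicates at n_fires = ",
      x$n_fires, "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
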