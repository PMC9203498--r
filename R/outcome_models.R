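# The six outcome-model structures, fitted as negative-binomial regressions
# under a uniform estimation contract:
#   naive            difference in means, cross-section
#   matched          same, on the caliper-matched subset
#   covariate        + biophysical covariates, fire varying intercept
#   did              two-period difference-in-differences, location-in-fire
#                    varying intercepts
#   panel            within-estimator panel regression, categorical
#                    time-since-treatment + weather covariates
#   did_interaction  DiD with effect modification along precip/temp/clay
#
# Engines: "ml" (Laplace maximum likelihood via glmmTMB, or glm.nb where no
# varying intercepts are present) with Wald intervals, or "mcmc" (full
# posterior via JAGS) with quantile intervals. Both return the same
# `outcome_fit` shape.

outcome_kinds <- function() {
  c("naive", "matched", "covariate", "did", "panel", "did_interaction")
}

#' Declare an outcome-model structure
#'
#' The model kind fixes everything else: the estimation frame, the
#' fixed-effect terms, and the varying-intercept grouping (none for
#' naive/matched; fire for covariate; location nested in fire for
#' did/panel/did_interaction). Options attempting to alter the grouping are
#' rejected.
#'
#' @param kind one of `naive`, `matched`, `covariate`, `did`, `panel`,
#'   `did_interaction`.
#' @param options reserved; supplying grouping overrides is an error.
#' @return object of class `outcome_spec`.
#' @export
make_spec <- function(kind, options = list()) {
  kind <- match.arg(kind, outcome_kinds())
  if (length(options)) {
    stop("options inconsistent with kind '", kind,
         "': grouping and terms are fixed by the model structure (got: ",
         paste(names(options), collapse = ", "), ")")
  }
  frame <- switch(kind,
                  naive = "cross_section", matched = "cross_section",
                  covariate = "cross_section",
                  did = "did_frame", did_interaction = "did_frame",
                  panel = "panel_frame")
  grouping <- switch(kind,
                     naive = character(), matched = character(),
                     covariate = "fire_id",
                     did = c("site_id", "fire_id"),
                     panel = c("site_id", "fire_id"),
                     did_interaction = c("site_id", "fire_id"))
  covariates <- switch(kind,
                       covariate = c("heatload", "elevation", "soil_clay", "soil_sand",
                                     "precip_nov_apr", "temp_feb_apr"),
                       panel = c("spring_precip", "spring_temp"),
                       did_interaction = c("precip_nov_apr", "temp_feb_apr", "soil_clay"),
                       character())
  beta_term <- switch(kind,
                      naive = "group", matched = "group", covariate = "group",
                      did = "time_post:group", panel = "treated_now",
                      did_interaction = "did")
  structure(list(kind = kind, frame = frame, grouping = grouping,
                 covariates = covariates, beta_term = beta_term,
                 response = "cover"),
            class = "outcome_spec")
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat("outcome_spec '", x$kind, "': frame = ", x$frame,
      "; varying intercepts = ",
      if (length(x$grouping)) paste(x$grouping, collapse = " + ") else "none",
      "; treatment term = ", x$beta_term, "\n", sep = "")
  invisible(x)
}

# Build the model data (standardized covariates, derived columns) and the
# fixed/RE formulas for a spec.
prepare_outcome_data <- function(spec, frame) {
  y <- frame[[spec$response]]
  if (is.null(y)) stop("frame lacks response column '", spec$response, "'")
  if (any(is.na(y)) || any(y < 0) || any(y != round(y))) {
    stop("response must be non-negative integers")
  }
  if (spec$frame %in% c("did_frame") && is.null(frame$time_post)) {
    stop("frame does not match spec: missing time_post (use build_frames()$",
         spec$frame, ")")
  }
  if (spec$frame == "panel_frame" && is.null(frame$time_f)) {
    stop("frame does not match spec: missing time_f (use build_frames()$panel_frame)")
  }
  record <- NULL
  dat <- frame
  if (length(spec$covariates)) {
    std <- standardize_covariates(dat, spec$covariates)
    dat <- std$data
    record <- std$record
  }
  fixed_terms <- switch(spec$kind,
    naive = "group", matched = "group",
    covariate = c("group", spec$covariates, "ecoregion"),
    did = c("time_post", "group", "time_post:group"),
    panel = c("time_f", "group", "treated_now", spec$covariates),
    did_interaction = {
      dat$did <- dat$time_post * dat$group
      extra <- character()
      for (nm in spec$covariates) {
        zc <- paste0("did_z_", nm); qc <- paste0("did_z2_", nm)
        dat[[zc]] <- dat$did * dat[[nm]]
        dat[[qc]] <- dat$did * dat[[nm]]^2
        extra <- c(extra, zc, qc)
      }
      c("time_post", "group", "did", extra)
    })
  if (spec$kind == "covariate") dat$ecoregion <- factor(dat$ecoregion)
  for (g in spec$grouping) dat[[g]] <- factor(dat[[g]])
  fixed_formula <- stats::as.formula(paste("cover ~", paste(fixed_terms, collapse = " + ")))
  full_formula <- if (length(spec$grouping)) {
    stats::as.formula(paste("cover ~", paste(fixed_terms, collapse = " + "), "+",
                            paste(sprintf("(1 | %s)", spec$grouping), collapse = " + ")))
  } else fixed_formula
  list(data = dat, fixed_formula = fixed_formula, full_formula = full_formula,
       record = record)
}

data_summary_quantiles <- function(frame) {
  nms <- intersect(c("precip_nov_apr", "temp_feb_apr", "soil_clay"), names(frame))
  out <- list()
  for (nm in nms) {
    out[[nm]] <- stats::quantile(frame[[nm]], probs = c(0.01, 0.99), names = FALSE)
  }
  out
}

#' Fit an outcome model
#'
#' @param spec an [make_spec()] `outcome_spec`.
#' @param frame the matching frame from [build_frames()] (for `matched`, the
#'   cross-section restricted to a matched set, see [matched_subset()]).
#' @param engine `"ml"` (Laplace ML, Wald intervals; the fast path) or
#'   `"mcmc"` (full posterior via JAGS; needs the rjags package).
#' @param seed integer; recorded, and used for the sampler and for any
#'   downstream coefficient draws.
#' @param chains,iter,warmup MCMC settings (defaults 4 chains, 2000
#'   iterations of which 1000 warmup).
#' @param check_convergence for MCMC, require split R-hat < 1.01 and bulk
#'   effective sample size > 400 per reported parameter (default TRUE);
#'   failure is an error carrying the diagnostics, never a silent return.
#' @return object of class `outcome_fit`: coefficient table with 95%
#'   intervals, treatment coefficient name, fixed-effect covariance, theta,
#'   varying-intercept SDs, fitted means, convergence report, seed, and (for
#'   MCMC) posterior draws.
#' @export
fit_outcome <- function(spec, frame, engine = c("ml", "mcmc"), seed = 1L,
                        chains = 4L, iter = 2000L, warmup = 1000L,
                        check_convergence = TRUE) {
  stopifnot(inherits(spec, "outcome_spec"))
  engine <- match.arg(engine)
  prep <- prepare_outcome_data(spec, frame)
  if (engine == "ml") {
    fit <- fit_outcome_ml(spec, prep, seed)
  } else {
    fit <- fit_outcome_mcmc(spec, prep, seed, chains, iter, warmup,
                            check_convergence)
  }
  fit$data_summary <- data_summary_quantiles(frame)
  fit$nobs <- nrow(prep$data)
  fit
}

fit_outcome_ml <- function(spec, prep, seed) {
  dat <- prep$data
  if (!length(spec$grouping)) {
    m <- tryCatch(suppressWarnings(MASS::glm.nb(prep$fixed_formula, data = dat)),
                  error = function(e) NULL)
    if (is.null(m) || !is.finite(m$theta)) {
      # theta estimation diverges when the data are un(der)dispersed around
      # the group means; the NB likelihood then approaches its Poisson limit
      m <- suppressWarnings(stats::glm(prep$fixed_formula, data = dat,
                                       family = MASS::negative.binomial(theta = 1e6)))
      m$theta <- 1e6
    }
    est <- stats::coef(m)
    V <- stats::vcov(m)
    theta <- m$theta
    sigma <- stats::setNames(numeric(0), character(0))
    fitted_mu <- as.numeric(stats::fitted(m))
    converged <- isTRUE(m$converged)
    diag_report <- list(engine = "glm.nb", converged = converged)
  } else {
    m <- glmmTMB::glmmTMB(prep$full_formula, family = glmmTMB::nbinom2,
                          data = dat,
                          control = glmmTMB::glmmTMBControl(profile = TRUE))
    est <- glmmTMB::fixef(m)$cond
    V <- stats::vcov(m)$cond
    theta <- glmmTMB::sigma(m)
    vc <- glmmTMB::VarCorr(m)$cond
    sigma <- vapply(vc, function(v) attr(v, "stddev")[[1]], numeric(1))
    fitted_mu <- as.numeric(stats::fitted(m))
    pdh <- isTRUE(m$sdr$pdHess)
    conv0 <- isTRUE(m$fit$convergence == 0)
    converged <- pdh && conv0
    diag_report <- list(engine = "glmmTMB", pdHess = pdh, optimizer_converged = conv0,
                        message = m$fit$message %||% "")
  }
  se <- sqrt(diag(as.matrix(V)))
  if (!converged || any(!is.finite(se))) {
    stop("outcome model did not converge: ",
         paste(names(diag_report), unlist(lapply(diag_report, format)),
               sep = "=", collapse = "; "))
  }
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), lwr = unname(est - 1.96 * se),
                      upr = unname(est + 1.96 * se), row.names = NULL)
  structure(list(
    spec = spec, engine = "ml", coefficients = coefs,
    beta_term = spec$beta_term, vcov = as.matrix(V), theta = theta,
    sigma = sigma, record = prep$record,
    xlevels = list(ecoregion = if (spec$kind == "covariate") levels(dat$ecoregion),
                   time_f = if (spec$kind == "panel") levels(dat$time_f)),
    fitted = fitted_mu, response = dat$cover,
    converged = TRUE, diagnostics = diag_report, seed = as.integer(seed),
    draws = NULL
  ), class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  b <- x$coefficients[x$coefficients$term == x$beta_term, ]
  cat("outcome_fit '", x$spec$kind, "' (", x$engine, "), n = ", x$nobs,
      ", theta = ", signif(x$theta, 4), "\n", sep = "")
  cat(sprintf("  treatment coefficient %s = %.4f [%.4f, %.4f]\n",
              x$beta_term, b$estimate, b$lwr, b$upr))
  if (length(x$sigma)) {
    cat("  varying-intercept SDs:",
        paste(sprintf("%s %.3f", names(x$sigma), x$sigma), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the treatment coefficient
#'
#' @param fit an `outcome_fit`.
#' @return one-row data.frame: estimate, se, lwr, upr.
#' @export
treatment_coef <- function(fit) {
  stopifnot(inherits(fit, "outcome_fit"))
  row <- fit$coefficients[fit$coefficients$term == fit$beta_term, , drop = FALSE]
  if (!nrow(row)) stop("treatment term not found in fit")
  row
}

# Coefficient draws: posterior draws when sampled, otherwise multivariate
# normal around the ML estimates (parametric approximation for intervals and
# Pr(effect >= 0)).
coef_draws <- function(fit, n_draws = 2000L, seed = NULL) {
  if (!is.null(fit$draws)) {
    d <- fit$draws
    if (nrow(d) > n_draws) d <- d[seq_len(n_draws), , drop = FALSE]
    return(d)
  }
  seed <- seed %||% fit$seed
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  with_keyed_seed(seed, 9L, 0L, {
    d <- MASS::mvrnorm(n_draws, mu = est, Sigma = fit$vcov)
    colnames(d) <- names(est)
    d
  })
}

# Linear-predictor row on the coefficient basis of a fit. `treated_now`
# switches the treatment term (and, for did_interaction, its modifiers);
# covariate values in `setting` are raw-scale and standardized via the fit's
# record; unset covariates sit at their means (z = 0).
build_lp_row <- function(fit, setting = list(), group = 1L, time = NULL,
                         treated_now = NULL) {
  spec <- fit$spec
  terms <- fit$coefficients$term
  x <- stats::setNames(numeric(length(terms)), terms)
  if ("(Intercept)" %in% terms) x["(Intercept)"] <- 1

  setting_z <- function(nm) {
    if (!is.null(setting[[nm]])) {
      if (is.null(fit$record) || !nm %in% names(fit$record$center)) {
        stop("covariate '", nm, "' is not a term of this model")
      }
      (setting[[nm]] - fit$record$center[[nm]]) / fit$record$scale[[nm]]
    } else 0
  }
  known <- c(spec$covariates, "ecoregion")
  bad <- setdiff(names(setting), known)
  if (length(bad)) stop("setting has value(s) for non-model term(s): ",
                        paste(bad, collapse = ", "))

  if (spec$kind %in% c("naive", "matched")) {
    x["group"] <- group
  } else if (spec$kind == "covariate") {
    x["group"] <- group
    for (nm in spec$covariates) x[nm] <- setting_z(nm)
    eco <- setting$ecoregion
    if (!is.null(eco)) {
      lev <- fit$xlevels$ecoregion
      if (!eco %in% lev) stop("unknown ecoregion: ", eco)
      dummy <- paste0("ecoregion", eco)
      if (dummy %in% terms) x[dummy] <- 1
    }
  } else if (spec$kind == "did") {
    if (is.null(time)) stop("missing term value: time (binary period, 0 or 1)")
    tp <- as.integer(time > 0)
    if (is.null(treated_now)) treated_now <- tp * group
    x["time_post"] <- tp
    x["group"] <- group
    x["time_post:group"] <- treated_now
  } else if (spec$kind == "panel") {
    if (is.null(time)) stop("missing term value: time (0..10)")
    lev <- fit$xlevels$time_f
    if (!as.character(time) %in% lev) stop("time not a panel level: ", time)
    if (time != lev[1]) x[paste0("time_f", time)] <- 1
    if (is.null(treated_now)) treated_now <- as.integer(time > 0) * group
    x["group"] <- group
    x["treated_now"] <- treated_now
    for (nm in spec$covariates) x[nm] <- setting_z(nm)
  } else if (spec$kind == "did_interaction") {
    if (is.null(time)) stop("missing term value: time (binary period, 0 or 1)")
    tp <- as.integer(time > 0)
    if (is.null(treated_now)) treated_now <- tp * group
    x["time_post"] <- tp
    x["group"] <- group
    x["did"] <- treated_now
    for (nm in spec$covariates) {
      z <- setting_z(nm)
      x[paste0("did_z_", nm)] <- treated_now * z
      x[paste0("did_z2_", nm)] <- treated_now * z^2
    }
  }
  x
}

#' Expected cover at a covariate setting
#'
#' `exp(linear predictor)` with varying intercepts marginalized at their mean
#' (zero on the log scale); the interval is propagated from the coefficient
#' uncertainty (posterior draws, or multivariate-normal draws around the ML
#' estimates).
#'
#' @param fit an `outcome_fit`.
#' @param setting named list of raw-scale covariate values (defaults: all
#'   covariates at their means, i.e. standardized zero).
#' @param group 0/1 treatment group.
#' @param time timepoint (binary period for DiD kinds; 0..10 for panel;
#'   ignored for cross-sectional kinds).
#' @param treated_now overrides the treatment indicator (`NULL` = factual:
#'   `group x post-period`); set 0 for the counterfactual.
#' @param n_draws,seed draws for the interval.
#' @return list: `estimate` (exact plug-in at the point coefficients), `lwr`,
#'   `upr` (2.5/97.5% over draws).
#' @export
predict_mean <- function(fit, setting = list(), group = 1L, time = NULL,
                         treated_now = NULL, n_draws = 2000L, seed = NULL) {
  stopifnot(inherits(fit, "outcome_fit"))
  x <- build_lp_row(fit, setting, group, time, treated_now)
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  point <- exp(sum(x * est))
  d <- coef_draws(fit, n_draws, seed)
  lp <- as.numeric(d %*% x)
  list(estimate = point,
       lwr = unname(stats::quantile(exp(lp), 0.025)),
       upr = unname(stats::quantile(exp(lp), 0.975)))
}
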