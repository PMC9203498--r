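# Response-scale treatment effects: the incremental effect
# exp(eta + beta) - exp(eta), recovery trajectories, and effect-modification
# curves along biophysical gradients.

#' Incremental treatment effect on the response scale
#'
#' In a log-link model the treatment indicator's coefficient is an
#' "incremental" effect: the percent-cover effect at a setting is
#' `exp(eta + beta) - exp(eta)`, with `eta` the treated-group, post-period
#' linear predictor excluding the treatment term. With
#' `include_intercept = TRUE` (default) `eta` includes the model intercept,
#' so the effect is the difference of predicted means in percent-cover
#' points; with `FALSE` it is the literal no-intercept form
#' `exp(group + time + group*time) - exp(group + time)`, which differs from
#' the former exactly by the factor `exp(alpha-hat)`.
#'
#' @param fit an `outcome_fit` of kind `did`, `panel`, or `did_interaction`
#'   (the group contrast of cross-sectional kinds is not an incremental
#'   effect; requesting it is an error).
#' @param setting named list of raw-scale covariate values (others at means).
#' @param time evaluation timepoint (default: post period / year 10).
#' @param include_intercept include `alpha` in `eta` (default TRUE).
#' @param n_draws,seed coefficient draws for the interval and
#'   `prob_nonnegative`.
#' @return object of class `treatment_effect`: `effect` (plug-in point
#'   estimate), `lwr`, `upr`, `prob_nonnegative` (share of draws with effect
#'   >= 0), and the evaluation setting.
#' @export
incremental_effect <- function(fit, setting = list(), time = NULL,
                               include_intercept = TRUE, n_draws = 2000L,
                               seed = NULL) {
  stopifnot(inherits(fit, "outcome_fit"))
  kind <- fit$spec$kind
  if (!kind %in% c("did", "panel", "did_interaction")) {
    stop("incremental effect is defined for did/panel/did_interaction fits; ",
         "'", kind, "' estimates a group contrast, not an incremental effect")
  }
  if (is.null(time)) time <- if (kind == "panel") 10L else 1L
  x1 <- build_lp_row(fit, setting, group = 1L, time = time, treated_now = 1L)
  x0 <- build_lp_row(fit, setting, group = 1L, time = time, treated_now = 0L)
  if (!include_intercept && "(Intercept)" %in% names(x1)) {
    x1["(Intercept)"] <- 0
    x0["(Intercept)"] <- 0
  }
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  point <- exp(sum(x1 * est)) - exp(sum(x0 * est))
  d <- coef_draws(fit, n_draws, seed)
  eff <- exp(as.numeric(d %*% x1)) - exp(as.numeric(d %*% x0))
  structure(list(
    effect = point,
    lwr = unname(stats::quantile(eff, 0.025)),
    upr = unname(stats::quantile(eff, 0.975)),
    prob_nonnegative = mean(eff >= 0),
    setting = setting, time = time, include_intercept = include_intercept,
    kind = kind
  ), class = "treatment_effect")
}

#' @export
print.treatment_effect <- function(x, ...) {
  cat(sprintf(paste0("treatment effect (%s, %s intercept): %.3f cover points ",
                     "[%.3f, %.3f]; Pr(effect >= 0) = %.3f\n"),
              x$kind, if (x$include_intercept) "with" else "without",
              x$effect, x$lwr, x$upr, x$prob_nonnegative))
  invisible(x)
}

#' Expected recovery trajectories, factual and counterfactual
#'
#' For a panel fit: expected cover of the treated group for years 0..10,
#' once with the treatment indicator following its factual history (on from
#' year 1) and once held at 0 (the no-treatment counterfactual), weather
#' covariates at their means.
#'
#' @param fit an `outcome_fit` of kind `panel`.
#' @param setting named list of raw-scale covariate values.
#' @param n_draws,seed coefficient draws for the intervals.
#' @return data.frame with per-year factual and counterfactual expected
#'   cover, 95% intervals, and their difference.
#' @export
recovery_trajectory <- function(fit, setting = list(), n_draws = 2000L,
                                seed = NULL) {
  stopifnot(inherits(fit, "outcome_fit"))
  if (fit$spec$kind != "panel") stop("recovery_trajectory needs a panel fit")
  times <- as.integer(fit$xlevels$time_f)
  rows <- lapply(times, function(t) {
    fac <- predict_mean(fit, setting, group = 1L, time = t,
                        treated_now = as.integer(t > 0), n_draws = n_draws,
                        seed = seed)
    cf <- predict_mean(fit, setting, group = 1L, time = t, treated_now = 0L,
                       n_draws = n_draws, seed = seed)
    data.frame(time = t,
               treated = fac$estimate, treated_lwr = fac$lwr, treated_upr = fac$upr,
               counterfactual = cf$estimate, counterfactual_lwr = cf$lwr,
               counterfactual_upr = cf$upr,
               effect = fac$estimate - cf$estimate)
  })
  do.call(rbind, rows)
}

#' Treatment-effect curve along a biophysical gradient
#'
#' Evaluates the incremental effect of a `did_interaction` fit along a grid
#' of one gradient (all other covariates at their means), optionally
#' overlaying whether treatment is likely (propensity > 0.5) at each grid
#' point under a supplied propensity model evaluated at the same setting.
#'
#' @param fit an `outcome_fit` of kind `did_interaction`.
#' @param gradient one of the fit's interaction covariates
#'   (`precip_nov_apr`, `temp_feb_apr`, `soil_clay`).
#' @param grid numeric grid of raw-scale gradient values; default 100 points
#'   spanning the 1st-99th percentiles of the fitting data.
#' @param setting raw-scale values for the other covariates.
#' @param propensity_fit optional `propensity_fit` for the likely/unlikely
#'   overlay.
#' @param n_grid grid size when `grid` is NULL.
#' @param n_draws,seed coefficient draws for the intervals.
#' @return data.frame: gradient value, effect with 95% interval,
#'   `prob_nonnegative`, and (with overlay) treatment probability and
#'   `likely_treated`.
#' @export
effect_curve <- function(fit, gradient, grid = NULL, setting = list(),
                         propensity_fit = NULL, n_grid = 100L,
                         n_draws = 2000L, seed = NULL) {
  stopifnot(inherits(fit, "outcome_fit"))
  if (fit$spec$kind != "did_interaction") {
    stop("effect_curve needs a did_interaction fit")
  }
  if (!gradient %in% fit$spec$covariates) {
    stop("gradient '", gradient, "' is not in the interaction specification (",
         paste(fit$spec$covariates, collapse = ", "), ")")
  }
  if (is.null(grid)) {
    q <- fit$data_summary[[gradient]]
    if (is.null(q)) stop("no stored percentiles for ", gradient,
                         "; supply `grid` explicitly")
    grid <- seq(q[1], q[2], length.out = n_grid)
  }
  rows <- lapply(grid, function(v) {
    st <- setting
    st[[gradient]] <- v
    eff <- incremental_effect(fit, st, time = 1L, include_intercept = TRUE,
                              n_draws = n_draws, seed = seed)
    out <- data.frame(value = v, effect = eff$effect, lwr = eff$lwr,
                      upr = eff$upr, prob_nonnegative = eff$prob_nonnegative)
    if (!is.null(propensity_fit)) {
      p <- predict_propensity(propensity_fit, st)
      out$p_treat <- p
      out$likely_treated <- p > 0.5
    }
    out
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- gradient
  out
}
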