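# Synthetic landscapes with the statistical structure the estimator ladder
# assumes: locations nested in fires, quadratic logistic treatment selection
# with an unobserved site-quality confounder, and bounded negative-binomial
# cover panels with parallel pre-treatment trends.

# Fixed generator-population constants (mean, sd) used to put covariates on a
# z-scale inside the selection and effect-modification surfaces. Using fixed
# constants (rather than sample moments) keeps every site's draws and
# propensity independent of how many other sites are generated.
gen_constants <- function() {
  list(
    prefire_cover   = c(12, 6),
    surviving_cover = c(2.5, 2.5),
    precip_nov_apr  = c(450, 165),
    temp_feb_apr    = c(5, 3.2),
    fire_size       = c(log(2000), 1),    # z computed on the log scale
    soil_clay       = c(20, 6.7),
    soil_sand       = c(45, 8),
    elevation       = c(1600, 320),
    heatload        = c(0.85, 0.12),
    dist_road       = c(log(1500), 0.9),  # z computed on the log scale
    spring_precip   = c(157.5, 73),
    spring_temp     = c(5.5, 2.83)
  )
}

gen_z <- function(sites, covariate) {
  k <- gen_constants()[[covariate]]
  x <- sites[[covariate]]
  if (covariate %in% c("fire_size", "dist_road")) x <- log(x)
  (x - k[1]) / k[2]
}

default_ecoregions <- function() {
  c("Snake River Plain" = 0.25, "Northern Basin" = 0.20,
    "Central Basin and Range" = 0.25, "Wyoming Basin" = 0.10,
    "Idaho Batholith" = 0.10, "Colorado Plateaus" = 0.10)
}

#' Construct a synthetic-landscape scenario configuration
#'
#' Holds the generator truth for a simulated study: landscape size, the
#' treatment-selection surface (quadratic logistic on observed covariates
#' plus an unobserved site-quality confounder), and the negative-binomial
#' cover model (baseline intercept, year effects, variance components,
#' dispersion, weather coefficients, and optional effect-modification terms).
#'
#' Defaults emulate the study system the package targets: ~1539 fires x 13
#' locations (~20,000 sites), selection favouring drier/warmer, more degraded
#' sites with interior optima on several gradients, baseline post-fire cover
#' around 2.5% recovering roughly three-fold over ten years, and a treatment
#' effect of `log(1.5)` on the log-mean scale.
#'
#' @param n_fires number of fires (default 1539).
#' @param locations_per_fire integer count, or length-2 range sampled per
#'   fire (default 13, giving ~20,000 locations).
#' @param seed integer; fully determines the landscape.
#' @param true_effect_beta log-scale treatment effect.
#' @param group_gamma direct group main effect on log cover (default 0; group
#'   differences normally arise through selection, not this term).
#' @param selection_intercept logit-scale intercept of the selection model.
#' @param selection_obs named list; each element `c(linear, quadratic)`
#'   coefficients on the generator z-scale of an observed covariate.
#' @param selection_eco named numeric vector of ecoregion intercept shifts.
#' @param selection_unobs coefficient on the unobserved site quality `u` in
#'   the selection logit (lambda_u; negative values make treated sites worse
#'   than they look).
#' @param confounder_sd SD of the unobserved site quality `u`, which enters
#'   the outcome log-mean with coefficient 1.
#' @param sigma_fire,sigma_loc SDs of fire- and location-level intercepts.
#' @param theta negative-binomial dispersion (variance mu + mu^2/theta).
#' @param baseline_alpha global log-mean intercept at year 0.
#' @param year_effects numeric length 11, log-scale year offsets tau_t for
#'   t = 0..10; `year_effects[1]` must be 0.
#' @param weather_coefs `c(precip, temp)` coefficients on standardized
#'   spring weather in the outcome log-mean.
#' @param interaction_coefs optional named list (`precip_nov_apr`,
#'   `temp_feb_apr`, `soil_clay`), each `c(linear, quadratic)`, multiplying
#'   the treatment indicator (effect modification along gradients).
#' @param pretrend_divergence difference in pre-fire log-cover slope between
#'   groups, per year (0 = parallel pre-trends).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_fires = 1539L,
                            locations_per_fire = 13L,
                            seed = 1L,
                            true_effect_beta = log(1.5),
                            group_gamma = 0,
                            selection_intercept = 1.75,
                            selection_obs = NULL,
                            selection_eco = NULL,
                            selection_unobs = -1.0,
                            confounder_sd = 0.6,
                            sigma_fire = 0.3,
                            sigma_loc = 0.35,
                            theta = 4,
                            baseline_alpha = log(2.0),
                            year_effects = log((2.0 + 0.40 * (0:10)) / 2.0),
                            weather_coefs = c(precip = 0.12, temp = 0.05),
                            interaction_coefs = NULL,
                            pretrend_divergence = 0) {
  if (!is.numeric(n_fires) || n_fires < 1) stop("n_fires must be a positive integer")
  if (theta <= 0) stop("theta must be > 0")
  if (any(c(confounder_sd, sigma_fire, sigma_loc) < 0)) stop("SDs must be >= 0")
  if (length(year_effects) != 11 || abs(year_effects[1]) > 1e-12) {
    stop("year_effects must have length 11 with year_effects[1] == 0")
  }
  if (!length(locations_per_fire) %in% c(1L, 2L)) {
    stop("locations_per_fire must be a count or a length-2 range")
  }
  if (is.null(selection_obs)) {
    selection_obs <- list(
      prefire_cover   = c(0.10, -0.50),
      surviving_cover = c(-0.60, 0),
      precip_nov_apr  = c(0.05, -0.45),
      temp_feb_apr    = c(0.20, -0.35),
      fire_size       = c(-0.15, 0),
      soil_clay       = c(0.30, 0),
      soil_sand       = c(-0.10, 0),
      elevation       = c(0, -0.20),
      heatload        = c(0.05, -0.10),
      dist_road       = c(0.10, -0.25)
    )
  }
  if (is.null(selection_eco)) {
    selection_eco <- c("Snake River Plain" = 0.5, "Northern Basin" = 0.2,
                       "Central Basin and Range" = 0.2, "Wyoming Basin" = 0,
                       "Idaho Batholith" = 0, "Colorado Plateaus" = -0.9)
  }
  bad <- setdiff(names(selection_obs), names(gen_constants()))
  if (length(bad)) stop("unknown selection covariate(s): ", paste(bad, collapse = ", "))
  if (!is.null(interaction_coefs)) {
    bad <- setdiff(names(interaction_coefs),
                   c("precip_nov_apr", "temp_feb_apr", "soil_clay"))
    if (length(bad)) stop("interaction_coefs allowed only on precip/temp/clay; got: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(
    n_fires = as.integer(n_fires), locations_per_fire = locations_per_fire,
    seed = as.integer(seed), true_effect_beta = true_effect_beta,
    group_gamma = group_gamma, selection_intercept = selection_intercept,
    selection_obs = selection_obs, selection_eco = selection_eco,
    selection_unobs = selection_unobs, confounder_sd = confounder_sd,
    sigma_fire = sigma_fire, sigma_loc = sigma_loc, theta = theta,
    baseline_alpha = baseline_alpha, year_effects = year_effects,
    weather_coefs = weather_coefs, interaction_coefs = interaction_coefs,
    pretrend_divergence = pretrend_divergence
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config:", x$n_fires, "fires x",
      paste(x$locations_per_fire, collapse = "-"), "locations; beta_true =",
      signif(x$true_effect_beta, 4), "; lambda_u =", x$selection_unobs,
      "; confounder_sd =", x$confounder_sd, "\n")
  invisible(x)
}

#' Canonical test scenarios
#'
#' Named presets covering the regimes the estimator ladder distinguishes:
#' \describe{
#'   \item{null_effect}{no treatment effect, nonzero observed selection,
#'     no confounding channel (every estimator should cover 0).}
#'   \item{selection_on_observables}{strong selection on measured climate and
#'     surviving cover, transmitted to the outcome through spring weather;
#'     matching/covariate adjustment fix it, the difference in means does not.}
#'   \item{selection_on_unobservables}{strongly negative selection on the
#'     unobserved site quality u; only the before/after designs (DiD, panel)
#'     recover the true positive effect.}
#'   \item{heterogeneous_effect}{effect modification along precipitation
#'     (interior optimum), temperature (cooler better) and clay gradients.}
#'   \item{divergent_trends}{violates parallel pre-trends by 0.05 log-cover
#'     per year, for diagnostics power checks.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed to [scenario_config()] (e.g. `n_fires`, `seed`).
#' @return a `scenario_config`.
#' @export
scenario_preset <- function(name, ...) {
  presets <- c("null_effect", "selection_on_observables",
               "selection_on_unobservables", "heterogeneous_effect",
               "divergent_trends")
  if (!is.character(name) || length(name) != 1 || !name %in% presets) {
    stop("unknown preset; valid presets: ", paste(presets, collapse = ", "))
  }
  args <- switch(name,
    null_effect = list(true_effect_beta = 0, selection_unobs = 0),
    selection_on_observables = list(
      selection_unobs = 0,
      selection_obs = list(
        prefire_cover   = c(0.10, -0.50),
        surviving_cover = c(-0.80, 0),
        precip_nov_apr  = c(-0.80, -0.30),
        temp_feb_apr    = c(0.50, -0.20),
        fire_size       = c(-0.15, 0),
        soil_clay       = c(0.30, 0),
        soil_sand       = c(-0.10, 0),
        elevation       = c(0, -0.20),
        heatload        = c(0.05, -0.10),
        dist_road       = c(0.10, -0.25)
      ),
      selection_intercept = 1.30,
      weather_coefs = c(precip = 0.30, temp = 0.10)
    ),
    selection_on_unobservables = list(selection_unobs = -2.2, confounder_sd = 0.65),
    heterogeneous_effect = list(
      selection_unobs = 0,
      interaction_coefs = list(
        precip_nov_apr = c(0.10, -0.15),
        temp_feb_apr   = c(-0.12, -0.08),
        soil_clay      = c(0, -0.08)
      )
    ),
    divergent_trends = list(pretrend_divergence = 0.05)
  )
  do.call(scenario_config, utils::modifyList(args, list(...)))
}

# Landscape generation ---------------------------------------------------------

#' Generate a synthetic landscape of burned locations
#'
#' Draws fires (with ecoregion, planar centre, fire-level climate and soil
#' means, fire size) and locations nested within them (site climate normals,
#' soils, terrain, pre-fire and surviving sagebrush cover, distance to road,
#' coordinates clustered around the fire centre), plus the latent truth:
#' unobserved site quality u, fire and location intercepts. Every draw comes
#' from a stream keyed by (seed, fire, site), so adding fires or sites never
#' perturbs existing ones.
#'
#' @param config a [scenario_config()].
#' @return list with `sites` (group unset, `NA`) and `truth` (data.frame of
#'   per-site u, intercepts, and — after [assign_treatment()] — propensity).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed
  n_fires <- config$n_fires
  eco_probs <- default_ecoregions()

  fire_rows <- vector("list", n_fires)
  for (k in seq_len(n_fires)) {
    fire_rows[[k]] <- with_keyed_seed(seed, 1L, k, {
      n_loc <- if (length(config$locations_per_fire) == 2L) {
        sample(config$locations_per_fire[1]:config$locations_per_fire[2], 1L)
      } else as.integer(config$locations_per_fire)
      data.frame(
        fire_id = sprintf("F%04d", k),
        ecoregion = sample(names(eco_probs), 1L, prob = eco_probs),
        center_x = stats::runif(1, 0, 1000), center_y = stats::runif(1, 0, 1000),
        precip_mu = rtruncnorm(1, 450, 160, 120, 950),
        temp_mu = rtruncnorm(1, 5, 3.2, -5.5, 11.5),
        elev_mu = rtruncnorm(1, 1600, 300, 700, 2600),
        clay_mu = rtruncnorm(1, 20, 6, 6, 45),
        fire_size = exp(stats::rnorm(1, log(2000), 1)),
        treatment_year = sample(1986:2001, 1L),
        alpha_fire = stats::rnorm(1, 0, config$sigma_fire),
        n_loc = n_loc
      )
    })
  }
  fires <- do.call(rbind, fire_rows)

  site_rows <- vector("list", n_fires)
  for (k in seq_len(n_fires)) {
    f <- fires[k, ]
    n_loc <- f$n_loc
    site_rows[[k]] <- with_keyed_seed(seed, 2L, k, {
      prefire <- pmin(pmax(stats::rnbinom(n_loc, mu = 12, size = 6), 1L), 60L)
      surv_frac <- stats::plogis(stats::rnorm(n_loc, -1.6, 0.8))
      clay <- round(rtruncnorm(n_loc, f$clay_mu, 3, 5, 50), 1)
      sand <- round(pmin(rtruncnorm(n_loc, 45, 8, 10, 75), 95 - clay), 1)
      data.frame(
        site_id = sprintf("%s_S%03d", f$fire_id, seq_len(n_loc)),
        fire_id = f$fire_id,
        coord_x = f$center_x + stats::rnorm(n_loc, 0, 3),
        coord_y = f$center_y + stats::rnorm(n_loc, 0, 3),
        ecoregion = f$ecoregion,
        group = NA_integer_,
        treatment_year = NA_integer_,
        prefire_cover = as.integer(prefire),
        surviving_cover = as.integer(round(prefire * surv_frac)),
        precip_nov_apr = round(pmin(pmax(f$precip_mu + stats::rnorm(n_loc, 0, 40), 100), 1000), 1),
        temp_feb_apr = round(pmin(pmax(f$temp_mu + stats::rnorm(n_loc, 0, 0.7), -6), 12), 2),
        fire_size = round(f$fire_size, 1),
        soil_clay = clay,
        soil_sand = sand,
        elevation = round(f$elev_mu + stats::rnorm(n_loc, 0, 120)),
        heatload = round(rtruncnorm(n_loc, 0.85, 0.12, 0.3, 1.2), 3),
        dist_road = round(exp(stats::rnorm(n_loc, log(1500), 0.9)), 1),
        u = stats::rnorm(n_loc, 0, config$confounder_sd),
        alpha_loc = stats::rnorm(n_loc, 0, config$sigma_loc)
      )
    })
  }
  all_sites <- do.call(rbind, site_rows)
  rownames(all_sites) <- NULL

  truth <- data.frame(
    site_id = all_sites$site_id, fire_id = all_sites$fire_id,
    u = all_sites$u,
    alpha_fire = fires$alpha_fire[match(all_sites$fire_id, fires$fire_id)],
    alpha_loc = all_sites$alpha_loc,
    propensity = NA_real_
  )
  sites <- all_sites[, setdiff(names(all_sites), c("u", "alpha_loc"))]
  fire_year <- fires$treatment_year[match(sites$fire_id, fires$fire_id)]
  attr(truth, "fire_treatment_year") <- fire_year
  log_info("generate_landscape: %d sites in %d fires", nrow(sites), n_fires)
  list(sites = sites, truth = truth)
}

selection_linear_predictor <- function(sites, truth, config) {
  lp <- rep(config$selection_intercept, nrow(sites))
  for (nm in names(config$selection_obs)) {
    b <- config$selection_obs[[nm]]
    z <- gen_z(sites, nm)
    lp <- lp + b[1] * z + b[2] * z^2
  }
  eco <- config$selection_eco[sites$ecoregion]
  eco[is.na(eco)] <- 0
  lp + unname(eco) + config$selection_unobs * truth$u
}

#' Assign treatment by logistic selection
#'
#' Computes each site's true propensity from the quadratic selection surface,
#' ecoregion shifts, and the unobserved quality `u`, then draws treatment
#' group Bernoulli(propensity). Treated sites inherit their fire's treatment
#' season as `treatment_year`.
#'
#' @param sites,truth output of [generate_landscape()].
#' @param config the same [scenario_config()].
#' @return list with updated `sites` (group, treatment_year) and `truth`
#'   (propensity filled in).
#' @export
assign_treatment <- function(sites, truth, config) {
  stopifnot(inherits(config, "scenario_config"))
  p <- stats::plogis(selection_linear_predictor(sites, truth, config))
  grp <- with_keyed_seed(config$seed, 4L, 0L, stats::rbinom(nrow(sites), 1L, p))
  sites$group <- as.integer(grp)
  fy <- attr(truth, "fire_treatment_year")
  sites$treatment_year <- ifelse(sites$group == 1L, fy, NA_integer_)
  truth$propensity <- p
  log_info("assign_treatment: treated fraction %.3f", mean(sites$group))
  list(sites = sites, truth = truth)
}

interaction_term <- function(sites, config) {
  if (is.null(config$interaction_coefs)) return(rep(0, nrow(sites)))
  out <- rep(0, nrow(sites))
  for (nm in names(config$interaction_coefs)) {
    b <- config$interaction_coefs[[nm]]
    z <- gen_z(sites, nm)
    out <- out + b[1] * z + b[2] * z^2
  }
  out
}

#' Simulate the cover panel
#'
#' Draws the negative-binomial cover observations for years 0..10 after
#' treatment (year 0 = pre-treatment baseline) and, optionally, `pre_years`
#' pre-fire years (negative time codes) for parallel-trends diagnostics.
#'
#' The log mean is
#' `alpha + alpha_fire + alpha_loc + u + tau_t + gamma*group +
#'  beta*treated_now + treated_now*h(site) + omega*weather`,
#' with `h` the effect-modification surface and weather standardized spring
#' precipitation/temperature drawn around each site's climate normals.
#' Draws are capped at 100 (cover is a percentage); the generator keeps means
#' low enough that capping is rare, and the realized capped fraction is
#' logged.
#'
#' @param sites,truth output of [assign_treatment()].
#' @param config the [scenario_config()].
#' @param pre_years number of pre-fire years to simulate (default 0).
#' @return data.frame of observations; attribute `potential_outcomes` holds
#'   per-site, per-timepoint expected cover under both treatment states at
#'   the realized weather (the generator's ground truth for recovery tests).
#' @export
simulate_cover_panel <- function(sites, truth, config, pre_years = 0L) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(is.na(sites$group))) stop("groups not assigned; run assign_treatment() first")
  n <- nrow(sites)
  times <- c(if (pre_years > 0) seq(-pre_years, -1L), 0:10)
  nt <- length(times)
  kc <- gen_constants()

  zp_site <- gen_z(sites, "precip_nov_apr")
  zt_site <- gen_z(sites, "temp_feb_apr")
  h_site <- interaction_term(sites, config)
  omega <- config$weather_coefs

  obs_list <- vector("list", n)
  po_list <- vector("list", n)
  n_capped <- 0L
  for (i in seq_len(n)) {
    draws <- with_keyed_seed(config$seed, 5L, i, {
      list(eps_p = stats::rnorm(nt), eps_t = stats::rnorm(nt),
           ug = stats::runif(nt))
    })
    spring_precip <- round(0.35 * sites$precip_nov_apr[i] + 45 * draws$eps_p, 1)
    spring_temp <- round(0.8 * sites$temp_feb_apr[i] + 1.5 + 1.2 * draws$eps_t, 2)
    wz_p <- (spring_precip - kc$spring_precip[1]) / kc$spring_precip[2]
    wz_t <- (spring_temp - kc$spring_temp[1]) / kc$spring_temp[2]

    g <- sites$group[i]
    base <- truth$alpha_fire[i] + truth$alpha_loc[i] + truth$u[i] +
      config$group_gamma * g + omega[1] * wz_p + omega[2] * wz_t

    post <- times >= 0
    tau <- ifelse(post, config$year_effects[pmax(times, 0) + 1L], 0)
    treated_now <- as.integer(post & times > 0 & g == 1L)

    lp0 <- ifelse(post,
                  config$baseline_alpha + base + tau,
                  log(max(sites$prefire_cover[i], 1)) + 0.02 * times +
                    config$pretrend_divergence * g * times +
                    0.5 * truth$alpha_loc[i] +
                    omega[1] * wz_p + omega[2] * wz_t)
    effect_term <- config$true_effect_beta + h_site[i]
    lp_fact <- lp0 + treated_now * effect_term
    if (any(lp_fact > 10)) {
      stop("log mean exceeded 10; rescale generator coefficients")
    }
    mu_fact <- exp(lp_fact)
    y <- stats::qnbinom(draws$ug, mu = mu_fact, size = config$theta)
    n_capped <- n_capped + sum(y > 100)
    y <- pmin(y, 100L)

    obs_list[[i]] <- data.frame(
      site_id = sites$site_id[i], time = times, cover = as.integer(y),
      spring_precip = spring_precip, spring_temp = spring_temp,
      treated_now = treated_now
    )
    # potential outcomes at realized weather, post period only
    mu1 <- exp(lp0[post] + as.integer(times[post] > 0) * effect_term)
    po_list[[i]] <- data.frame(
      site_id = sites$site_id[i], time = times[post],
      mu_untreated = exp(lp0[post]), mu_treated = mu1
    )
  }
  observations <- do.call(rbind, obs_list)
  rownames(observations) <- NULL
  frac_capped <- n_capped / (n * nt)
  log_info("simulate_cover_panel: %d observations; capped fraction %.5f",
           nrow(observations), frac_capped)
  if (frac_capped > 0.001) {
    warning(sprintf("%.2f%% of draws hit the 100%% cover cap; consider lowering generator means",
                    100 * frac_capped))
  }
  attr(observations, "potential_outcomes") <- do.call(rbind, po_list)
  observations
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_landscape()], [assign_treatment()]
#' and [simulate_cover_panel()].
#'
#' @inheritParams simulate_cover_panel
#' @param config a [scenario_config()] or preset name for [scenario_preset()].
#' @param ... overrides when `config` is a preset name.
#' @return list with `sites`, `observations`, `truth`, `config`.
#' @export
simulate_landscape <- function(config, pre_years = 0L, ...) {
  if (is.character(config)) config <- scenario_preset(config, ...)
  land <- generate_landscape(config)
  land <- assign_treatment(land$sites, land$truth, config)
  observations <- simulate_cover_panel(land$sites, land$truth, config,
                                       pre_years = pre_years)
  truth <- land$truth
  attr(truth, "potential_outcomes") <- attr(observations, "potential_outcomes")
  list(sites = land$sites, observations = observations, truth = truth,
       config = config)
}
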