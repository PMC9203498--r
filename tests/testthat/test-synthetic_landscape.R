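# Generator: determinism, selection mechanics, and the statistical
# structure downstream estimators rely on.

test_that("a fixed seed fully determines the landscape; adding fires appends", {
  a <- suppressMessages(simulate_landscape(
    scenario_preset("null_effect", n_fires = 4L, seed = 42L,
                    locations_per_fire = 3L)))
  b <- suppressMessages(simulate_landscape(
    scenario_preset("null_effect", n_fires = 4L, seed = 42L,
                    locations_per_fire = 3L)))
  expect_identical(a$sites, b$sites)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth$u, b$truth$u)

  wider <- suppressMessages(simulate_landscape(
    scenario_preset("null_effect", n_fires = 6L, seed = 42L,
                    locations_per_fire = 3L)))
  n <- nrow(a$sites)
  cols <- setdiff(names(a$sites), c("group", "treatment_year"))
  expect_identical(wider$sites[seq_len(n), cols], a$sites[, cols])
  expect_identical(wider$truth$u[seq_len(n)], a$truth$u)
})

test_that("configuration errors are explicit", {
  expect_error(scenario_config(n_fires = 0), "n_fires")
  expect_error(scenario_config(theta = -1), "theta")
  expect_error(scenario_config(year_effects = rep(0, 5)), "year_effects")
  expect_error(scenario_preset("bogus"), "null_effect.*divergent_trends")
  expect_error(scenario_config(selection_obs = list(nonsense = c(1, 0))),
               "nonsense")
  expect_error(scenario_config(interaction_coefs = list(elevation = c(1, 0))),
               "precip/temp/clay")
})

test_that("confounder_sd = 0 silences the unobserved quality", {
  sim <- suppressMessages(simulate_landscape(
    scenario_config(n_fires = 5L, locations_per_fire = 4L, seed = 2L,
                    confounder_sd = 0)))
  expect_true(all(sim$truth$u == 0))
})

test_that("null selection yields propensity 1/2 everywhere", {
  cfg <- scenario_config(n_fires = 50L, seed = 9L, selection_intercept = 0,
                         selection_obs = zero_selection(),
                         selection_eco = zero_eco(), selection_unobs = 0)
  land <- suppressMessages(generate_landscape(cfg))
  land <- suppressMessages(assign_treatment(land$sites, land$truth, cfg))
  expect_true(all(land$truth$propensity == 0.5))
  expect_gt(mean(land$sites$group), 0.44)
  expect_lt(mean(land$sites$group), 0.56)
})

test_that("negative selection on u makes treated sites worse than they look", {
  sim <- cached_sim("selection_on_unobservables", n_fires = 100L, seed = 11L)
  gap <- mean(sim$truth$u[sim$sites$group == 1]) -
    mean(sim$truth$u[sim$sites$group == 0])
  expect_lt(gap, -0.3)
})

test_that("quadratic precipitation selection peaks at an interior bin", {
  sim <- cached_sim("selection_on_unobservables", n_fires = 200L, seed = 21L)
  bins <- cut(sim$sites$precip_nov_apr,
              stats::quantile(sim$sites$precip_nov_apr, probs = seq(0, 1, 0.2)),
              include.lowest = TRUE, labels = FALSE)
  freq <- tapply(sim$sites$group, bins, mean)
  expect_true(which.max(freq) %in% 2:4)
})

test_that("realized treated/counterfactual cover ratio matches exp(beta_true)", {
  sim <- cached_sim("selection_on_unobservables", n_fires = 150L, seed = 31L)
  po <- attr(sim$truth, "potential_outcomes")
  treated_ids <- sim$sites$site_id[sim$sites$group == 1L]
  obs <- sim$observations
  post <- obs$site_id %in% treated_ids & obs$time > 0
  po_post <- po[po$site_id %in% treated_ids & po$time > 0, ]
  po_post <- po_post[order(po_post$site_id, po_post$time), ]
  obs_post <- obs[post, ]
  obs_post <- obs_post[order(obs_post$site_id, obs_post$time), ]
  ratio <- mean(obs_post$cover) / mean(po_post$mu_untreated)
  expect_equal(ratio, 1.5, tolerance = 0.02)
})

test_that("with every component silenced, mean cover converges to exp(alpha)", {
  cfg <- scenario_config(n_fires = 385L, locations_per_fire = 13L, seed = 8L,
                         true_effect_beta = 0, selection_unobs = 0,
                         confounder_sd = 0, sigma_fire = 0, sigma_loc = 0,
                         year_effects = rep(0, 11),
                         weather_coefs = c(precip = 0, temp = 0))
  sim <- suppressMessages(simulate_landscape(cfg))
  expect_equal(mean(sim$observations$cover), exp(cfg$baseline_alpha),
               tolerance = 0.01)
})

test_that("pre-treatment group trajectories stay parallel across replicates", {
  ok <- 0L
  for (s in 1:10) {
    sim <- suppressMessages(simulate_landscape(
      scenario_preset("selection_on_unobservables", n_fires = 30L,
                      seed = 100L + s), pre_years = 4L))
    pre <- sim$observations[sim$observations$time < 0, ]
    chk <- parallel_trends_check(sim$sites, pre)
    if (abs(chk$slope_difference$estimate) < 2 * chk$slope_difference$se) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 9L)
})

test_that("observed selection reproduces the drier/warmer/more-degraded pattern", {
  sim <- cached_sim("selection_on_observables", n_fires = 150L, seed = 41L)
  s <- sim$sites
  expect_lt(mean(s$precip_nov_apr[s$group == 1]), mean(s$precip_nov_apr[s$group == 0]))
  expect_gt(mean(s$temp_feb_apr[s$group == 1]), mean(s$temp_feb_apr[s$group == 0]))
  expect_lt(mean(s$surviving_cover[s$group == 1]), mean(s$surviving_cover[s$group == 0]))
})

test_that("preset definitions encode their scenario", {
  expect_identical(scenario_preset("null_effect")$true_effect_beta, 0)
  expect_gt(abs(scenario_preset("null_effect")$selection_obs$surviving_cover[1]), 0)
  sou <- scenario_preset("selection_on_unobservables")
  expect_lt(sou$selection_unobs, 0)
  expect_equal(sou$true_effect_beta, log(1.5))
  het <- scenario_preset("heterogeneous_effect")
  expect_lt(het$interaction_coefs$precip_nov_apr[2], 0)
  expect_lt(het$interaction_coefs$temp_feb_apr[1], 0)
})
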