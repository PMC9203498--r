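# Response-scale effects: the incremental-effect identity, trajectories,
# and effect-modification curves.

test_that("the no-intercept incremental effect is forced arithmetic", {
  fit <- make_toy_fit("did", toy_did_coefs(alpha = 1.3, tau = log(4),
                                           gamma = 0, beta = log(1.5)))
  e <- incremental_effect(fit, include_intercept = FALSE)
  expect_equal(e$effect, 6 - 4, tolerance = 1e-12)

  fit0 <- make_toy_fit("did", toy_did_coefs(beta = 0, gamma = 0.7, tau = 1.1))
  expect_equal(incremental_effect(fit0)$effect, 0, tolerance = 1e-12)
  expect_equal(incremental_effect(fit0, include_intercept = FALSE)$effect, 0,
               tolerance = 1e-12)
})

test_that("group-contrast fits cannot produce an incremental effect", {
  toy <- data.frame(site_id = 1:8, cover = c(rep(2L, 4), rep(4L, 4)),
                    group = rep(c(1L, 0L), each = 4))
  fit <- fit_outcome(make_spec("naive"), toy)
  expect_error(incremental_effect(fit), "group contrast")
})

test_that("incremental effect equals the predicted-mean difference exactly", {
  set.seed(31)
  for (i in 1:20) {
    fit <- make_toy_fit("did", toy_did_coefs(alpha = rnorm(1), tau = rnorm(1),
                                             gamma = rnorm(1), beta = rnorm(1)))
    e <- incremental_effect(fit, seed = i)
    p1 <- predict_mean(fit, group = 1L, time = 1L, treated_now = 1L, seed = i)
    p0 <- predict_mean(fit, group = 1L, time = 1L, treated_now = 0L, seed = i)
    expect_equal(e$effect, p1$estimate - p0$estimate, tolerance = 1e-10)
    # printed no-intercept form differs exactly by the factor exp(alpha-hat)
    e0 <- incremental_effect(fit, include_intercept = FALSE, seed = i)
    a <- fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"]
    expect_equal(e$effect, exp(a) * e0$effect, tolerance = 1e-10)
    # monotonicity of exp: the effect carries beta's sign
    beta <- fit$coefficients$estimate[fit$coefficients$term == "time_post:group"]
    expect_identical(sign(e$effect), sign(beta))
  }
})

test_that("prob_nonnegative is exactly the draw fraction with effect >= 0", {
  draws <- cbind("(Intercept)" = rnorm(500, 0, 0.1),
                 time_post = rnorm(500, 1, 0.2),
                 group = rnorm(500, 0, 0.2),
                 "time_post:group" = rnorm(500, 0.1, 0.5))
  fit <- make_toy_fit("did", toy_did_coefs(), draws = draws)
  e <- incremental_effect(fit)
  eff_draws <- exp(draws %*% c(1, 1, 1, 1)) - exp(draws %*% c(1, 1, 1, 0))
  expect_identical(e$prob_nonnegative, mean(eff_draws >= 0))
})

test_that("trajectories start equal at year 0 and collapse when beta = 0", {
  est <- c("(Intercept)" = log(3),
           stats::setNames(seq(0.1, 1, 0.1), paste0("time_f", 1:10)),
           group = 0.2, treated_now = 0, spring_precip = 0.1,
           spring_temp = 0.05)
  fit0 <- make_toy_fit("panel", est)
  tr <- recovery_trajectory(fit0)
  expect_equal(tr$treated, tr$counterfactual, tolerance = 1e-12)

  est["treated_now"] <- log(1.4)
  fit1 <- make_toy_fit("panel", est)
  tr1 <- recovery_trajectory(fit1)
  expect_equal(tr1$treated[tr1$time == 0], tr1$counterfactual[tr1$time == 0],
               tolerance = 1e-12)
  # year-10 gap is the incremental effect at the same setting
  e10 <- incremental_effect(fit1, time = 10L)
  expect_equal(tr1$effect[tr1$time == 10], e10$effect, tolerance = 1e-10)
})

test_that("effect curves flatten without modification and honor their domain", {
  est <- c("(Intercept)" = log(3), time_post = 0.8, group = 0.1,
           did = log(1.5),
           did_z_precip_nov_apr = 0, did_z2_precip_nov_apr = 0,
           did_z_temp_feb_apr = 0, did_z2_temp_feb_apr = 0,
           did_z_soil_clay = 0, did_z2_soil_clay = 0)
  rec <- std_record(center = c(precip_nov_apr = 450, temp_feb_apr = 5,
                               soil_clay = 20),
                    scale = c(precip_nov_apr = 165, temp_feb_apr = 3.2,
                              soil_clay = 6.7))
  fit <- make_toy_fit("did_interaction", est, record = rec)
  grid <- seq(200, 800, length.out = 7)
  cv <- effect_curve(fit, "precip_nov_apr", grid = grid)
  scalar <- incremental_effect(fit)$effect
  expect_equal(cv$effect, rep(scalar, 7), tolerance = 1e-10)

  one <- effect_curve(fit, "precip_nov_apr", grid = 505)
  expect_equal(one$effect,
               incremental_effect(fit, setting = list(precip_nov_apr = 505))$effect,
               tolerance = 1e-10)

  expect_error(effect_curve(fit, "elevation", grid = grid),
               "not in the interaction specification")
  did_fit <- make_toy_fit("did", toy_did_coefs())
  expect_error(effect_curve(did_fit, "precip_nov_apr", grid = grid),
               "did_interaction")
})

test_that("fitted effect curves recover the generator's interior optimum", {
  sim <- cached_sim("heterogeneous_effect", n_fires = 200L, seed = 5L)
  frames <- cached_frames(sim)
  fit <- fit_outcome(make_spec("did_interaction"), frames$did_frame, seed = 5)
  cv <- effect_curve(fit, "precip_nov_apr", n_grid = 15L, seed = 5)
  est_opt <- cv$precip_nov_apr[which.max(cv$effect)]
  # truth optimum on the same grid: h(z) = 0.10 z - 0.15 z^2 peaks at z = 1/3
  z <- (cv$precip_nov_apr - 450) / 165
  truth_opt <- cv$precip_nov_apr[which.max(0.10 * z - 0.15 * z^2)]
  step <- diff(cv$precip_nov_apr[1:2])
  expect_lte(abs(est_opt - truth_opt), step + 1e-9)
  # cooler sites gain more along the temperature gradient
  cvt <- effect_curve(fit, "temp_feb_apr", n_grid = 15L, seed = 5)
  expect_gt(cvt$effect[1], cvt$effect[15])
})
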