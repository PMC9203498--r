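# Propensity model, greedy caliper matching, and balance reporting.

test_that("null selection gives flat scores and coefficient intervals around 0", {
  cfg <- scenario_config(n_fires = 120L, seed = 3L, selection_intercept = 0,
                         selection_obs = zero_selection(),
                         selection_eco = zero_eco(), selection_unobs = 0)
  sim <- suppressMessages(simulate_landscape(cfg))
  fit <- suppressWarnings(fit_propensity(sim$sites))
  expect_gt(mean(fit$scores), 0.45)
  expect_lt(mean(fit$scores), 0.55)
  covars <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  frac_zero <- mean(covars$lwr <= 0 & covars$upr >= 0)
  expect_gte(frac_zero, 0.8)
})

test_that("known selection coefficients are recovered within 3 SE", {
  # strong terms of the observed-selection surface, on the generator z-scale
  truth_gen <- c(surviving_cover = -0.80, soil_clay = 0.30,
                 precip_nov_apr = -0.80, temp_feb_apr = 0.50,
                 "I(precip_nov_apr^2)" = -0.30, "I(temp_feb_apr^2)" = -0.20)
  gen_sd <- c(surviving_cover = 2.5, soil_clay = 6.7, precip_nov_apr = 165,
              temp_feb_apr = 3.2)
  hits <- 0L; total <- 0L
  for (s in 1:4) {
    sim <- suppressMessages(simulate_landscape(
      scenario_preset("selection_on_observables", n_fires = 385L,
                      seed = 200L + s)))
    fit <- fit_propensity(sim$sites)
    co <- fit$coefficients
    for (term in names(truth_gen)) {
      base <- sub("^I\\((.*)\\^2\\)$", "\\1", term)
      ratio <- fit$record$scale[[base]] / gen_sd[[base]]
      adj <- if (grepl("\\^2", term)) ratio^2 else ratio
      truth_fit_scale <- truth_gen[[term]] * adj
      row <- co[co$term == term, ]
      total <- total + 1L
      if (abs(row$estimate - truth_fit_scale) <= 3 * row$se) hits <- hits + 1L
    }
    # fitted logits track the true selection surface
    lp_true <- restordid:::selection_linear_predictor(sim$sites, sim$truth,
                                                     sim$config)
    expect_gt(stats::cor(stats::qlogis(fit$scores), lp_true), 0.9)
  }
  expect_gte(hits / total, 0.9)
})

test_that("degenerate and separated inputs error informatively", {
  s2 <- toy_sites(2, group = c(1L, 0L))
  expect_error(fit_propensity(s2), "2 sites per treatment group")
  # perfectly separated single covariate
  s4 <- toy_sites(4, group = c(1L, 1L, 0L, 0L),
                  elevation = c(2000, 2100, 1000, 1100))
  expect_error(
    suppressWarnings(fit_propensity(
      s4, covariates = list(linear = "elevation", quadratic = character()))),
    "separation")
})

test_that("the worked matching example resolves as documented", {
  pairs <- greedy_caliper_match(
    c(t1 = 0.20, t2 = 0.80), c(c1 = 0.25, c2 = 0.50, c3 = 0.90), caliper = 0.10)
  expect_identical(nrow(pairs), 2L)
  expect_identical(pairs$control_site_id[pairs$treated_site_id == "t1"], "c1")
  expect_identical(pairs$control_site_id[pairs$treated_site_id == "t2"], "c3")

  tie <- greedy_caliper_match(c(t = 0.5), c(c = 0.5), caliper = 0.1)
  expect_identical(nrow(tie), 1L)
  expect_identical(tie$score_distance, 0)

  # zero caliper: only exact ties match
  z <- greedy_caliper_match(c(t1 = 0.4, t2 = 0.6), c(c1 = 0.4, c2 = 0.61),
                            caliper = 0)
  expect_identical(nrow(z), 1L)
  expect_identical(z$treated_site_id, "t1")
})

test_that("greedy matching respects its invariants and the brute-force count", {
  set.seed(77)
  for (i in 1:20) {
    nt <- sample(2:6, 1); nc <- sample(2:6, 1)
    ts <- stats::setNames(round(runif(nt), 3), paste0("t", seq_len(nt)))
    cs <- stats::setNames(round(runif(nc), 3), paste0("c", seq_len(nc)))
    cal <- runif(1, 0.05, 0.3)
    pairs <- greedy_caliper_match(ts, cs, cal)
    expect_false(any(duplicated(pairs$control_site_id)))
    expect_false(any(duplicated(pairs$treated_site_id)))
    expect_true(all(pairs$score_distance <= cal + 1e-12))
    bf <- brute_force_match(unname(ts), unname(cs), cal)
    # greedy is not always optimal in count, but never beats the optimum and
    # stays within one pair of it on these small problems
    expect_lte(nrow(pairs), bf$count)
    expect_gte(nrow(pairs), bf$count - 1L)
  }
})

test_that("matching is deterministic under permutation of the input order", {
  set.seed(5)
  ts <- stats::setNames(runif(8), paste0("t", 1:8))
  cs <- stats::setNames(runif(8), paste0("c", 1:8))
  p1 <- greedy_caliper_match(ts, cs, 0.15)
  perm_t <- sample(seq_along(ts)); perm_c <- sample(seq_along(cs))
  p2 <- greedy_caliper_match(ts[perm_t], cs[perm_c], 0.15)
  o1 <- p1[order(p1$treated_site_id), ]
  o2 <- p2[order(p2$treated_site_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("balance arithmetic is exact in forced cases", {
  d <- data.frame(group = rep(c(1L, 0L), each = 3),
                  x = c(0, 1, 2, -1, 0, 1))
  b <- balance_table(d, "x")
  expect_equal(b$smd_before, 1)
  d2 <- data.frame(group = rep(c(1L, 0L), each = 3), x = rep(c(1, 2, 3), 2))
  expect_equal(balance_table(d2, "x")$smd_before, 0)
  # zero pooled SD is flagged, not an error
  d3 <- data.frame(group = rep(c(1L, 0L), each = 3), x = rep(5, 6))
  b3 <- balance_table(d3, "x")
  expect_equal(b3$smd_before, 0)
  expect_true(b3$smd_flag)
})

test_that("matching improves covariate balance under observed selection", {
  for (s in 1:3) {
    sim <- cached_sim("selection_on_observables", n_fires = 100L,
                      seed = 300L + s)
    fit <- fit_propensity(sim$sites)
    ms <- suppressMessages(match_sites(fit))
    bal <- suppressMessages(balance_table(sim$sites, matched = ms))
    expect_lt(max(abs(bal$smd_after)), max(abs(bal$smd_before)))
  }
})

test_that("refitting the propensity model on the matched subset flattens it", {
  sim <- cached_sim("selection_on_observables", n_fires = 150L, seed = 41L)
  fit <- fit_propensity(sim$sites)
  ms <- suppressMessages(match_sites(fit))
  msites <- suppressMessages(matched_subset(sim$sites, ms))
  refit <- suppressWarnings(fit_propensity(msites))
  covars <- refit$coefficients[refit$coefficients$term != "(Intercept)", ]
  expect_gte(mean(covars$lwr <= 0 & covars$upr >= 0), 0.8)
})
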