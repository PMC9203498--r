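# Panel I/O, validation, standardization, and frame construction.

test_that("write/read round trip reproduces site and observation records", {
  sim <- cached_sim("selection_on_unobservables", n_fires = 2L, seed = 1L,
                    locations_per_fire = 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(write_panel(sim$sites, sim$observations, path))
  loaded <- suppressMessages(load_panel(path))
  expect_equal(loaded$sites, sim$sites, tolerance = 1e-12)
  expect_identical(loaded$observations$cover, sim$observations$cover)
  obs_expected <- sim$observations
  attr(obs_expected, "potential_outcomes") <- NULL
  expect_equal(loaded$observations, obs_expected, tolerance = 1e-12)
})

test_that("schema and validation errors name the offending column or row", {
  sim <- cached_sim("selection_on_unobservables", n_fires = 2L, seed = 1L,
                    locations_per_fire = 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(write_panel(sim$sites, sim$observations, path))

  d <- utils::read.csv(path)
  d2 <- d[, setdiff(names(d), "soil_clay")]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d2, p2, row.names = FALSE)
  expect_error(load_panel(p2), "soil_clay")

  d3 <- d
  d3$cover[4] <- 101L
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d3, p3, row.names = FALSE)
  expect_error(suppressMessages(load_panel(p3)), "\\[0, 100\\].*4")

  d4 <- rbind(d, d[1, ])
  p4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d4, p4, row.names = FALSE)
  expect_error(suppressMessages(load_panel(p4)), "duplicate")

  # schema mapping renames file columns to the canonical names
  d5 <- d
  names(d5)[names(d5) == "cover"] <- "sagebrush_pct"
  p5 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d5, p5, row.names = FALSE)
  loaded <- suppressMessages(load_panel(p5, schema = c(cover = "sagebrush_pct")))
  expect_identical(loaded$observations$cover, d$cover[order(d$site_id, d$time)])
})

test_that("sites lacking a baseline row are rejected, the rest kept", {
  sim <- cached_sim("selection_on_unobservables", n_fires = 2L, seed = 1L,
                    locations_per_fire = 3L)
  keep3 <- sim$sites$site_id[1:3]
  sites <- sim$sites[sim$sites$site_id %in% keep3, ]
  obs <- sim$observations[sim$observations$site_id %in% keep3, ]
  # strip the baseline row of the second site
  obs <- obs[!(obs$site_id == keep3[2] & obs$time == 0), ]
  path <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(write_panel(sites, obs, path))
  expect_warning(loaded <- suppressMessages(load_panel(path)), "baseline")
  expect_identical(nrow(loaded$sites), 2L)
  expect_setdiff <- setdiff(loaded$sites$site_id, keep3[c(1, 3)])
  expect_length(expect_setdiff, 0)
  expect_identical(nrow(loaded$observations), 2L * 11L)
})

test_that("standardization is exact arithmetic, idempotent, and invertible", {
  d <- data.frame(x = c(1, 2, 3))
  out <- standardize_covariates(d, "x")
  expect_equal(out$data$x, c(-1, 0, 1))
  expect_equal(out$record$center[["x"]], 2)
  expect_equal(out$record$scale[["x"]], 1)

  again <- standardize_covariates(out$data, "x")
  expect_equal(again$data$x, out$data$x, tolerance = 1e-10)

  raw <- data.frame(x = rnorm(50, 10, 3))
  s <- standardize_covariates(raw, "x")
  expect_lt(abs(mean(s$data$x)), 1e-10)
  expect_lt(abs(stats::sd(s$data$x) - 1), 1e-10)
  back <- invert_standardization(apply_standardization(raw, s$record), s$record)
  expect_equal(back$x, raw$x, tolerance = 1e-10)

  expect_error(standardize_covariates(data.frame(x = c(5, 5, 5)), "x"),
               "zero-variance.*x")
})

test_that("standardization record survives a JSON round trip", {
  rec <- standardize_covariates(data.frame(a = rnorm(20), b = runif(20)),
                                c("a", "b"))$record
  path <- withr::local_tempfile(fileext = ".json")
  write_standardization(rec, path)
  rec2 <- read_standardization(path)
  expect_equal(rec2$center, rec$center)
  expect_equal(rec2$scale, rec$scale)
})

test_that("frame row counts follow (sites kept) x {1, 2, post_year + 1}", {
  sim <- cached_sim("selection_on_unobservables", n_fires = 2L, seed = 1L,
                    locations_per_fire = 3L)
  frames <- suppressMessages(build_frames(sim$sites, sim$observations))
  expect_identical(nrow(frames$cross_section), 6L)
  expect_identical(nrow(frames$did_frame), 12L)
  expect_identical(nrow(frames$panel_frame), 66L)
  expect_setequal(unique(frames$did_frame$time), c(0L, 10L))
  expect_identical(levels(frames$panel_frame$time_f), as.character(0:10))

  # sensitivity re-run: year 8 as the post period
  f8 <- suppressMessages(build_frames(sim$sites, sim$observations, post_year = 8L))
  expect_setequal(unique(f8$did_frame$time), c(0L, 8L))
  expect_identical(nrow(f8$panel_frame), 6L * 9L)

  # a site missing a required timepoint is dropped from every frame
  obs_missing <- sim$observations[
    !(sim$observations$site_id == sim$sites$site_id[1] &
        sim$observations$time == 10), ]
  fdrop <- suppressMessages(build_frames(sim$sites, obs_missing))
  expect_identical(nrow(fdrop$cross_section), 5L)
  expect_identical(nrow(fdrop$did_frame), 10L)
  expect_identical(nrow(fdrop$panel_frame), 55L)
  expect_identical(attr(fdrop, "dropped_sites"), 1L)

  expect_error(suppressMessages(build_frames(sim$sites, sim$observations,
                                             post_year = 11L)))
})

test_that("treated_now inconsistencies are caught by validation", {
  sim <- cached_sim("selection_on_unobservables", n_fires = 2L, seed = 1L,
                    locations_per_fire = 3L)
  obs <- sim$observations
  obs$treated_now[obs$time == 0][1] <- 1L
  expect_error(validate_observations(obs), "treated_now")

  obs2 <- sim$observations
  untreated <- sim$sites$site_id[sim$sites$group == 0L][1]
  expect_false(is.na(untreated))  # fixed seed: fixture has both groups
  obs2$treated_now[obs2$site_id == untreated & obs2$time == 5] <- 1L
  expect_error(validate_observations(obs2, sim$sites), "untreated")
})
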