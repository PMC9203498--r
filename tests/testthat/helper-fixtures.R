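# Shared fixtures: cached simulated landscapes, hand-built outcome fits for
# closed-form oracles, and a brute-force matching oracle.

fixture_cache <- new.env(parent = emptyenv())

# Memoized landscape simulation so several tests can share one draw.
cached_sim <- function(preset, n_fires, seed, pre_years = 0L, ...) {
  key <- paste(preset, n_fires, seed, pre_years, sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- suppressMessages(suppressWarnings(
      simulate_landscape(scenario_preset(preset, n_fires = n_fires, seed = seed, ...),
                         pre_years = pre_years)))
  }
  fixture_cache[[key]]
}

cached_frames <- function(sim) {
  key <- paste("frames", sim$config$seed, sim$config$n_fires, nrow(sim$sites),
               sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- suppressMessages(build_frames(sim$sites, sim$observations))
  }
  fixture_cache[[key]]
}

# A selection surface with every coefficient zero (for null-selection tests).
zero_selection <- function() {
  nms <- c("prefire_cover", "surviving_cover", "precip_nov_apr", "temp_feb_apr",
           "fire_size", "soil_clay", "soil_sand", "elevation", "heatload",
           "dist_road")
  sel <- lapply(nms, function(x) c(0, 0))
  names(sel) <- nms
  sel
}

zero_eco <- function() {
  stats::setNames(rep(0, 6), names(restordid:::default_ecoregions()))
}

# Build an outcome_fit directly from named coefficients, for exact algebraic
# oracles on the prediction/effect machinery.
make_toy_fit <- function(kind, est, vcov = NULL, record = NULL,
                         draws = NULL, fitted = numeric(0),
                         response = integer(0), theta = 5) {
  spec <- make_spec(kind)
  if (is.null(vcov)) {
    vcov <- diag(1e-6, length(est))
    dimnames(vcov) <- list(names(est), names(est))
  }
  se <- sqrt(diag(vcov))
  structure(list(
    spec = spec, engine = "ml",
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se), lwr = unname(est - 1.96 * se),
                              upr = unname(est + 1.96 * se), row.names = NULL),
    beta_term = spec$beta_term, vcov = vcov, theta = theta,
    sigma = numeric(0), record = record,
    xlevels = list(ecoregion = NULL,
                   time_f = if (kind == "panel") as.character(0:10)),
    fitted = fitted, response = response, converged = TRUE,
    diagnostics = list(), seed = 1L, draws = draws,
    data_summary = list(), nobs = length(response)
  ), class = "outcome_fit")
}

toy_did_coefs <- function(alpha = 0, tau = log(4), gamma = 0, beta = log(1.5)) {
  c("(Intercept)" = alpha, "time_post" = tau, "group" = gamma,
    "time_post:group" = beta)
}

std_record <- function(center, scale) {
  structure(list(center = center, scale = scale),
            class = "standardization_record")
}

# Brute-force 1:1 caliper matching oracle: maximum pair count, then minimum
# total distance, by bitmask dynamic programming over the control set.
brute_force_match <- function(treated_scores, control_scores, caliper) {
  Tn <- length(treated_scores); Cn <- length(control_scores)
  stopifnot(Cn <= 12)
  n_states <- bitwShiftL(1L, Cn)
  # value[i, mask]: best (count, -dist) completing treated i..Tn with controls in mask
  count <- matrix(0L, Tn + 1L, n_states)
  dist <- matrix(0, Tn + 1L, n_states)
  for (i in Tn:1) {
    for (mask in 0:(n_states - 1L)) {
      best_c <- count[i + 1L, mask + 1L]
      best_d <- dist[i + 1L, mask + 1L]
      for (c in seq_len(Cn)) {
        bit <- bitwShiftL(1L, c - 1L)
        if (bitwAnd(mask, bit) == 0L) next
        d <- abs(treated_scores[i] - control_scores[c])
        if (d > caliper) next
        nm <- bitwAnd(mask, bitwNot(bit))
        cc <- count[i + 1L, nm + 1L] + 1L
        dd <- dist[i + 1L, nm + 1L] + d
        if (cc > best_c || (cc == best_c && dd < best_d)) {
          best_c <- cc; best_d <- dd
        }
      }
      count[i, mask + 1L] <- best_c
      dist[i, mask + 1L] <- best_d
    }
  }
  list(count = count[1L, n_states], total_distance = dist[1L, n_states])
}

# Minimal valid site table for propensity/balance toys.
toy_sites <- function(n, group, elevation = NULL, seed = 1) {
  set.seed(seed)
  data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    fire_id = "F0001",
    coord_x = runif(n), coord_y = runif(n),
    ecoregion = "Snake River Plain",
    group = group,
    treatment_year = NA_integer_,
    prefire_cover = 10L, surviving_cover = 2L,
    precip_nov_apr = rnorm(n, 450, 100), temp_feb_apr = rnorm(n, 5, 2),
    fire_size = exp(rnorm(n, log(2000), 0.5)),
    soil_clay = rnorm(n, 20, 4), soil_sand = rnorm(n, 45, 5),
    elevation = elevation %||% rnorm(n, 1600, 200),
    heatload = rnorm(n, 0.85, 0.1),
    dist_road = exp(rnorm(n, log(1500), 0.5))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
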