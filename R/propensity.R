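# Propensity-score estimation (quadratic logistic GLMM with ecoregion
# varying intercepts), greedy caliper nearest-neighbour matching, and
# covariate balance reporting.

default_propensity_covariates <- function() {
  list(
    linear = c("prefire_cover", "surviving_cover", "precip_nov_apr",
               "temp_feb_apr", "fire_size", "soil_clay", "soil_sand",
               "elevation", "heatload", "dist_road"),
    quadratic = c("temp_feb_apr", "precip_nov_apr", "elevation", "heatload",
                  "dist_road", "prefire_cover")
  )
}

#' Fit the treatment-probability (propensity) model
#'
#' Logistic mixed model for treatment occurrence with linear terms for the
#' biophysical covariates, quadratic terms for those gradients where managers
#' plausibly select intermediate values (temperature, precipitation,
#' elevation, heatload, distance from road, pre-fire cover), and a varying
#' intercept for ecoregion. Covariates are centered and scaled internally
#' (one SD); quadratic terms are squares of the standardized variable. The
#' strongly right-skewed covariates (fire size, distance from road) are
#' log-transformed before standardization, the usual treatment for areas and
#' distances.
#'
#' @param sites site table (see [load_panel()]); `group` must be 0/1.
#' @param covariates list with `linear` and `quadratic` character vectors;
#'   defaults to the standard biophysical set.
#' @return object of class `propensity_fit`: coefficient table with 95%
#'   Wald intervals, per-site scores in (0, 1), the standardization record,
#'   and the fitted model.
#' @export
fit_propensity <- function(sites, covariates = default_propensity_covariates()) {
  validate_sites(sites)
  if (min(table(factor(sites$group, levels = 0:1))) < 2) {
    stop("need at least 2 sites per treatment group")
  }
  lin <- covariates$linear
  quad <- intersect(covariates$quadratic, lin)
  log_covs <- intersect(c("fire_size", "dist_road"), lin)
  dat <- sites
  for (nm in log_covs) dat[[nm]] <- log(dat[[nm]])
  std <- standardize_covariates(dat, lin)
  dat <- std$data
  dat$ecoregion <- factor(dat$ecoregion)

  rhs <- c(lin, sprintf("I(%s^2)", quad))
  multi_eco <- nlevels(dat$ecoregion) > 1
  form <- stats::as.formula(paste(
    "group ~", paste(rhs, collapse = " + "),
    if (multi_eco) "+ (1 | ecoregion)" else ""))

  X <- stats::model.matrix(stats::as.formula(paste("~", paste(rhs, collapse = "+"))), dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ", paste(drop_cols, collapse = ", "))
  }

  fit <- glmmTMB::glmmTMB(form, family = stats::binomial(), data = dat)
  fe <- glmmTMB::fixef(fit)$cond
  if (any(!is.finite(fe)) || any(abs(fe) > 15)) {
    stop("apparent complete separation in the propensity model; ",
         "consider regularizing or removing covariates")
  }
  se <- sqrt(diag(stats::vcov(fit)$cond))
  coefs <- data.frame(term = names(fe), estimate = unname(fe), se = unname(se),
                      lwr = unname(fe - 1.96 * se), upr = unname(fe + 1.96 * se))
  scores <- stats::predict(fit, type = "response")
  if (any(scores <= 0 | scores >= 1)) {
    scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  }
  eco_int <- tryCatch(glmmTMB::ranef(fit)$cond$ecoregion, error = function(e) NULL)
  structure(list(
    coefficients = coefs,
    ecoregion_intercepts = eco_int,
    scores = stats::setNames(as.numeric(scores), as.character(sites$site_id)),
    group = stats::setNames(sites$group, as.character(sites$site_id)),
    record = std$record,
    covariates = list(linear = lin, quadratic = quad, log = log_covs),
    model = fit
  ), class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("propensity_fit:", length(x$scores), "sites;",
      nrow(x$coefficients), "fixed-effect terms\n")
  print(utils::head(x$coefficients, 8))
  invisible(x)
}

#' Predict treatment probability at a covariate setting
#'
#' Population-level prediction (ecoregion intercept at its mean, zero on the
#' logit scale) at raw-scale covariate values; unspecified covariates sit at
#' their standardization means.
#'
#' @param fit a `propensity_fit`.
#' @param setting named list/vector of raw-scale covariate values.
#' @return probability in (0, 1).
#' @export
predict_propensity <- function(fit, setting = list()) {
  stopifnot(inherits(fit, "propensity_fit"))
  z <- stats::setNames(rep(0, length(fit$covariates$linear)), fit$covariates$linear)
  for (nm in names(setting)) {
    if (!nm %in% names(z)) stop("unknown covariate in setting: ", nm)
    v <- setting[[nm]]
    if (nm %in% fit$covariates$log) v <- log(v)
    z[nm] <- (v - fit$record$center[[nm]]) / fit$record$scale[[nm]]
  }
  fe <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  lp <- fe[["(Intercept)"]] +
    sum(fe[fit$covariates$linear] * z[fit$covariates$linear]) +
    sum(fe[sprintf("I(%s^2)", fit$covariates$quadratic)] *
          z[fit$covariates$quadratic]^2)
  stats::plogis(unname(lp))
}

#' Greedy caliper matching on raw score vectors
#'
#' The core matching rule, exposed for direct use: treated units processed
#' in descending score order (ties broken by id), each paired with its
#' nearest unmatched control within the caliper, 1:1 without replacement.
#'
#' @param treated_scores,control_scores named numeric vectors of scores
#'   (names are unit ids).
#' @param caliper maximum allowed score distance within a pair.
#' @return data.frame of pairs (`treated_site_id`, `control_site_id`,
#'   `score_distance`).
#' @export
greedy_caliper_match <- function(treated_scores, control_scores, caliper) {
  t_ids <- names(treated_scores)
  t_ids <- t_ids[order(-treated_scores[t_ids], t_ids)]
  ord <- order(control_scores, names(control_scores))
  c_ids <- names(control_scores)[ord]
  c_scores <- unname(control_scores[ord])
  used <- rep(FALSE, length(c_ids))

  pairs <- vector("list", length(t_ids))
  np <- 0L
  for (tid in t_ids) {
    st <- treated_scores[[tid]]
    pos <- findInterval(st, c_scores)
    lo <- pos; hi <- pos + 1L
    best <- NA_integer_; bestd <- Inf
    while (lo >= 1L || hi <= length(c_ids)) {
      dlo <- if (lo >= 1L) abs(st - c_scores[lo]) else Inf
      dhi <- if (hi <= length(c_ids)) abs(c_scores[hi] - st) else Inf
      if (min(dlo, dhi) >= bestd) break
      if (dlo <= dhi) {
        if (!used[lo] && dlo < bestd) { best <- lo; bestd <- dlo }
        lo <- lo - 1L
      } else {
        if (!used[hi] && dhi < bestd) { best <- hi; bestd <- dhi }
        hi <- hi + 1L
      }
    }
    if (!is.na(best) && bestd <= caliper) {
      used[best] <- TRUE
      np <- np + 1L
      pairs[[np]] <- data.frame(treated_site_id = tid,
                                control_site_id = c_ids[best],
                                score_distance = bestd)
    }
  }
  pairs <- if (np) do.call(rbind, pairs[seq_len(np)]) else
    data.frame(treated_site_id = character(), control_site_id = character(),
               score_distance = numeric())
  rownames(pairs) <- NULL
  pairs
}

#' Greedy caliper nearest-neighbour matching
#'
#' 1:1 matching without replacement on the propensity score. Treated sites
#' are processed in descending score order (hardest to match first), ties
#' broken by site id; each is paired with the nearest unmatched control
#' within the caliper, `caliper_multiplier` x SD of the scores (or of their
#' logits with `caliper_scale = "logit"`). Deterministic: permuting input
#' rows yields the same pair set.
#'
#' @param fit a `propensity_fit` (scores for all sites).
#' @param caliper_multiplier caliper width in score-SD units (default 0.2).
#' @param caliper_scale `"score"` (default) or `"logit"`: whether the SD is
#'   taken of the scores or of their logits (distance is measured on the same
#'   scale).
#' @return object of class `matched_set`: data.frame `pairs`
#'   (`treated_site_id`, `control_site_id`, `score_distance`), ids of
#'   unmatched sites, the caliper used, and ecoregions eliminated entirely.
#' @export
match_sites <- function(fit, caliper_multiplier = 0.2,
                        caliper_scale = c("score", "logit")) {
  stopifnot(inherits(fit, "propensity_fit"))
  caliper_scale <- match.arg(caliper_scale)
  s <- fit$scores
  if (caliper_scale == "logit") s <- stats::qlogis(s)
  caliper <- caliper_multiplier * stats::sd(s)

  ids <- names(s)
  pairs <- greedy_caliper_match(s[ids[fit$group == 1L]],
                                s[ids[fit$group == 0L]], caliper)
  if (!nrow(pairs)) warning("no pairs found within the caliper")
  matched_ids <- c(pairs$treated_site_id, pairs$control_site_id)
  unmatched <- setdiff(ids, matched_ids)
  log_info("match_sites: %d pairs; %d site(s) unmatched; caliper %.5f (%s scale)",
           nrow(pairs), length(unmatched), caliper, caliper_scale)
  structure(list(pairs = pairs, unmatched = unmatched, caliper = caliper,
                 caliper_scale = caliper_scale,
                 caliper_multiplier = caliper_multiplier),
            class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  cat("matched_set:", nrow(x$pairs), "pairs;", length(x$unmatched),
      "unmatched; caliper", signif(x$caliper, 4), "on", x$caliper_scale, "scale\n")
  invisible(x)
}

#' Subset sites to a matched set
#'
#' @param sites site table.
#' @param matched a `matched_set`.
#' @return the matched sites, with a logged report of ecoregions whose sites
#'   were eliminated entirely by matching.
#' @export
matched_subset <- function(sites, matched) {
  stopifnot(inherits(matched, "matched_set"))
  keep <- sites$site_id %in% c(matched$pairs$treated_site_id,
                               matched$pairs$control_site_id)
  out <- sites[keep, , drop = FALSE]
  gone <- setdiff(unique(sites$ecoregion), unique(out$ecoregion))
  if (length(gone)) {
    log_info("matched_subset: ecoregion(s) eliminated entirely: %s",
             paste(gone, collapse = ", "))
  }
  attr(out, "eliminated_ecoregions") <- gone
  out
}

#' Covariate balance before and after matching
#'
#' Per covariate: group means and the standardized mean difference
#' (difference of means over the pooled SD), before matching and — when a
#' `matched_set` is supplied — after.
#'
#' @param sites site table with groups assigned.
#' @param covariate_names covariates to report (default: propensity set).
#' @param matched optional `matched_set`.
#' @return data.frame with one row per covariate; `smd_flag` marks zero
#'   pooled-SD cases (SMD reported as 0).
#' @export
balance_table <- function(sites,
                          covariate_names = default_propensity_covariates()$linear,
                          matched = NULL) {
  if (min(table(factor(sites$group, levels = 0:1))) < 1) {
    stop("need at least 1 site per treatment group")
  }
  smd_one <- function(dat, nm) {
    xt <- dat[[nm]][dat$group == 1L]
    xc <- dat[[nm]][dat$group == 0L]
    pooled <- sqrt((stats::var(xt) + stats::var(xc)) / 2)
    if (!is.finite(pooled) || pooled == 0) {
      c(mean_treated = mean(xt), mean_control = mean(xc), smd = 0, flag = 1)
    } else {
      c(mean_treated = mean(xt), mean_control = mean(xc),
        smd = (mean(xt) - mean(xc)) / pooled, flag = 0)
    }
  }
  before <- t(vapply(covariate_names, smd_one, numeric(4), dat = sites))
  out <- data.frame(covariate = covariate_names,
                    mean_treated = before[, 1], mean_control = before[, 2],
                    smd_before = before[, 3], smd_flag = before[, 4] == 1,
                    row.names = NULL)
  if (!is.null(matched)) {
    msites <- matched_subset(sites, matched)
    after <- t(vapply(covariate_names, smd_one, numeric(4), dat = msites))
    out$mean_treated_matched <- after[, 1]
    out$mean_control_matched <- after[, 2]
    out$smd_after <- after[, 3]
  }
  out
}
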