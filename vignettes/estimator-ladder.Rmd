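---
title: "Selection bias and the estimator ladder: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection bias and the estimator ladder: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(restordid)
```

## The inferential problem

Post-fire seeding of sagebrush is applied where managers expect it to be
needed: drier, warmer sites with little surviving cover. Any observational
comparison of seeded and unseeded land therefore mixes the effect of seeding
with the effect of being the kind of site that gets seeded. Part of that
selection is measurable (climate normals, soils, pre- and post-fire cover);
part is not (microsite soil-water conditions, invasion pressure, grazing
history). The package organises the standard quasi-experimental responses to
this problem into one ladder, so the consequences of each assumption can be
seen side by side on data where the truth is known.

## Outcome models and their assumptions

All six structures are negative-binomial (NB2) regressions for integer
percent cover: `Var(y) = mu + mu^2/theta`. Cover is remotely sensed as a
fraction of a pixel, hence a count-like, overdispersed, non-negative
quantity; the 100% ceiling is deliberately *not* modelled in the
likelihood. Instead `predictive_check()` verifies that fitted models place
essentially no mass above 100 — the honest version of bounding, given that
fitted means sit far below the ceiling.

* **naive / matched** — intercept and a group contrast only. Unbiased only
  under random treatment assignment (naive) or after conditioning on all
  selection-relevant observables (matched).
* **covariate** — adds the standard biophysical control set (heatload,
  elevation, clay, sand, precipitation and temperature normals, ecoregion)
  and a fire-level varying intercept. Same identifying assumption as
  matching, expressed through regression adjustment.
* **did** — two periods (year 0 pre-treatment baseline, year 10), group,
  period, and their interaction, with location-within-fire varying
  intercepts. Identifies the effect under *parallel trends*: absent
  treatment, group trajectories would have moved in parallel. Anything
  time-invariant — measured or not — cancels.
* **panel** — eleven periods with categorical time-since-treatment, a
  treatment indicator switching on after year 0, and the year's spring
  weather. Extends DiD to timepoint-specific shocks and measured
  time-varying confounders.
* **did_interaction** — the DiD structure plus interactions of the
  treatment term with standardized precipitation, temperature, and clay
  (linear and quadratic), for effect modification along gradients.

Two structural decisions deserve note. First, the residual term that often
appears written in such linear predictors is interpreted here as the NB
sampling variability itself, not an extra observation-level random effect:
a free observation-level effect is not identified alongside `theta`.
Second, the matched model does not model pair identity; matching selects
the sample, the model remains the group contrast.

Varying intercepts are hierarchical normal on the log scale, location
nested within fire. Cluster-robust sandwich standard errors are the
econometric alternative; they are out of scope here — clustering is handled
inside the model.

## Estimation contract

`fit_outcome()` offers two engines returning identical object shapes:

* `ml` (default): Laplace maximum likelihood via glmmTMB (plain NB
  regression via glm.nb when no varying intercepts are present), Wald
  95% intervals. Interval statements and `Pr(effect >= 0)` use draws from
  the multivariate normal around the estimates. This is the fast path used
  by the replicate studies.
* `mcmc`: full posterior in JAGS with weakly informative priors —
  Normal(0, 2.5) on standardized-scale coefficients, half-Normal(0, 1) on
  varying-intercept SDs, Gamma(2, 0.1) on `theta`. Convergence is enforced,
  not reported: split R-hat < 1.01 and effective sample size > 400 per
  parameter, otherwise an error carrying the diagnostics. Defaults are 4
  chains of 2000 iterations (1000 warmup); models with weakly identified
  variance components (two observations per location in DiD) need more,
  and the tests use 6000/2000 there.

Point estimates of response-scale quantities are exact plug-ins at the
point coefficients, so algebraic identities hold to machine precision:
`incremental_effect()` equals the `predict_mean()` difference, and the
literal no-intercept form of the effect differs from the predicted-mean
form exactly by `exp(alpha-hat)`. The package defaults to the
predicted-mean convention (percent-cover points), keeping the no-intercept
form behind `include_intercept = FALSE`: the printed formula omits the
intercept and varying intercepts, but magnitudes communicated in
percent-cover points require the intercept, and supporting both makes the
relationship testable rather than ambiguous.

## Standardization and time coding

Continuous covariates are centered and scaled by one standard deviation at
fit time; the `standardization_record` travels with each fit so predictions
and effect curves accept raw-scale settings. Quadratic terms are squares of
the *standardized* variable (standardize-then-square), keeping linear and
quadratic coefficients on comparable scales. Fire size and road distance
are log-transformed before standardization in the propensity model — the
usual treatment for strongly right-skewed areas and distances.

Time is years since treatment. For untreated sites the clock is anchored to
their fire's treatment season, so "year 0" is pre-treatment for both groups
and calendar-aligned within a fire. This is an interpretive choice: no
treatment occurred at untreated sites, so their clock must borrow an
anchor, and the fire's season is the only natural one. Observations with
missing weather are dropped (complete cases) with a logged count rather
than imputed — the estimators assume complete cases, and imputation would
smuggle in a second model.

## Propensity model and matching

Treatment occurrence is modelled as a Bernoulli GLMM (logit link) with
linear terms for the biophysical set, quadratic terms where selection for
intermediate values is plausible (temperature, precipitation, elevation,
heatload, road distance, pre-fire cover — heatload is included in both the
linear and quadratic sets), and an ecoregion varying intercept.

Matching is greedy 1:1 nearest-neighbour without replacement: treated sites
in descending score order (hardest to match first — the standard heuristic),
ties broken by site id, each paired to the nearest unmatched control within
the caliper. The caliper is `0.2 x SD(scores)` by default; the phrase
"standard deviation of the propensity score" is read as the SD of the
estimated scores, with the logit-scale alternative exposed via
`caliper_scale = "logit"` but not default. Greedy matching is deterministic
under row permutation, which optimal matching implementations often are
not; the tests verify its pair count against an exhaustive
maximum-cardinality oracle on small problems (greedy concedes at most one
pair there). Ecoregions eliminated entirely by matching are reported, since
effects estimated on the matched sample no longer speak for them.

## The synthetic landscape

`scenario_config()` holds the generator truth; its defaults are the study
conditions the package targets: ~1539 fires x 13 locations (~20,000 sites),
two treatment groups, and a `log(1.5)` treatment effect. Specifics:

* **Covariates.** Fire-level climate/soil means (precipitation normals
  ~450 ± 160 mm truncated to 100-1000; spring temperature ~5 ± 3.2 °C in
  [-6, 12]; elevation ~1600 ± 300 m; clay 5-50%) with site-level jitter;
  lognormal fire sizes and road distances; pre-fire cover >= 1% (the
  study-system inclusion rule) with surviving cover a random thinning of
  it; coordinates clustered around fire centres (for spatial diagnostics
  only).
* **Selection.** A quadratic logistic surface on the generator's fixed
  z-scale, ecoregion shifts, plus `lambda_u * u` with `u ~ N(0,
  confounder_sd)` the unobserved site quality. The default surface peaks at
  intermediate pre-fire cover, precipitation near 460 mm, and mild spring
  temperatures, and declines with surviving cover — the qualitative
  selection pattern the estimators must confront.
* **Outcome.** `log mu = alpha + alpha_k + alpha_j + u + tau_t +
  gamma*group + beta*treated_now + treated_now*h(site) + omega*weather`,
  NB(theta = 4), capped at 100. Baseline `alpha = log(2)` (typical
  surviving cover shortly after fire) recovering roughly three-fold over
  ten years; the cap binds for well under 0.1% of draws and the realized
  fraction is logged. Spring weather is drawn around each site's climate
  normals, which is precisely how *observed* selection leaks into the
  outcome: select on dry normals and you select on dry springs. `u` enters
  both selection and outcome — the confounding DiD absorbs because it is
  time-invariant.
* **Randomness.** Every draw comes from a stream keyed by (seed, fire,
  site), so a fixed seed is bit-reproducible and enlarging a landscape
  appends draws without perturbing existing ones.

Preset calibration: the magnitude of unobserved confounding has no
canonical value, so `selection_on_unobservables` sets `lambda_u = -2.2`,
`confounder_sd = 0.65` — chosen by forward calculation so the naive
estimator's expected bias clearly reverses the sign of a `log(1.5)` effect,
reproducing the qualitative contrast the ladder exists to display, not any
particular published estimate. Similarly `selection_on_observables`
strengthens the linear climate selection and the weather coefficients so
that regression adjustment and matching visibly repair a bias the naive
contrast visibly has.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: spatial autocorrelation beyond fire
clustering (no random fields), temporal autocorrelation in weather,
non-stationary treatment effects, measurement error in remotely sensed
cover, cheatgrass/grazing covariates, or fire-spread geometry. The
generator validates estimator logic, not ecological realism.

## Diagnostics

* **Parallel trends** — group-mean pre-period trajectories plus a
  quantitative slope contrast from `lm(cover ~ time*group)` with HC3
  heteroskedasticity-consistent standard errors. The visual check remains
  available (the trajectory table); the quantitative flag makes the check
  testable. Detection of a 0.05 log-cover/yr divergence is reliable at the
  ~5,000-site scale the tests use.
* **Moran's I correlogram** — row-standardized binary weights per distance
  bin, permutation null (999 permutations by default, seeded, two-sided
  around `-1/(n-1)`). Bin breaks and permutation count are configurable
  since no canonical values exist. The 4-point alternating configuration
  (`I = -1` exactly) anchors the implementation, and an independent
  implementation (ape) cross-checks the statistic in the tests. The minimum
  input size is 4 locations so that this anchor case is computable;
  inference at such sizes is of course meaningless.
* **Predictive checks** — within-sample MAE against fitted means (varying
  intercepts included) and NB replicate datasets, reporting any mass above
  the 100% bound.
* **Recovery studies** — replicate landscapes per scenario, every estimator
  refitted per replicate (ML path), aggregating bias, interval coverage,
  and sign-error fraction. Replicate failures are recorded per replicate,
  never fatal, and the seed list makes the study exactly reproducible.

## Problem sizes and numerical choices

The replicate studies run at `n_fires = 100` (~1,300 sites; 30 replicates),
where the panel GLMM fits in seconds and the three headline studies
complete in minutes on one CPU — large enough that coverage and sign
statistics are meaningful, small enough to iterate. Single-landscape
analyses in the tests use 150-400 fires. glmmTMB fits use profiled Laplace
likelihood; degenerate saturated data (zero residual variance) make the NB
dispersion diverge, in which case the fit falls back to the Poisson-limit
NB with fixed large `theta`, which leaves the mean structure exact.
Propensity scores are clamped away from 0/1 by 1e-12 before matching;
apparent separation (|standardized coefficient| > 15) is an error, not a
warning.

## Known limitations

Wald intervals on variance components are unreliable near zero (the usual
Laplace caveat); the MCMC engine is the remedy where those intervals
matter. The matched estimator inherits greedy matching's order dependence
in principle, though the documented ordering makes it deterministic. The
panel model's weather coefficients are not causally interpretable in the
presence of lagged weather effects — they are controls, not estimates of
weather effects. And the ladder's top rung still assumes treatment effects
are stable over time and predictors are exogenous; violations of those
assumptions are outside what any estimator here can repair.
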