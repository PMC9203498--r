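#' @keywords internal
"_PACKAGE"

# Canonical column sets ------------------------------------------------------

site_columns <- function() {
  c("site_id", "fire_id", "coord_x", "coord_y", "ecoregion", "group",
    "treatment_year", "prefire_cover", "surviving_cover", "precip_nov_apr",
    "temp_feb_apr", "fire_size", "soil_clay", "soil_sand", "elevation",
    "heatload", "dist_road")
}

obs_columns <- function() {
  c("site_id", "time", "cover", "spring_precip", "spring_temp", "treated_now")
}

#' Validate a table of site records
#'
#' Checks the invariants of the site table: cover fields in \[0, 100\],
#' soil clay + sand not exceeding 100, binary treatment group, and one fire
#' per site.
#'
#' @param sites data.frame with one row per location (see [load_panel()] for
#'   the column contract).
#' @return The input, invisibly, after validation.
#' @export
validate_sites <- function(sites) {
  need <- setdiff(site_columns(), "treatment_year")
  missing <- setdiff(need, names(sites))
  if (length(missing)) {
    stop("site table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site_id in site table: ",
         paste(utils::head(sites$site_id[duplicated(sites$site_id)], 3), collapse = ", "))
  }
  for (col in c("prefire_cover", "surviving_cover")) {
    bad <- which(sites[[col]] < 0 | sites[[col]] > 100)
    if (length(bad)) {
      stop(sprintf("%s outside [0, 100] at row(s) %s", col,
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  bad <- which(sites$soil_clay + sites$soil_sand > 100)
  if (length(bad)) {
    stop("soil_clay + soil_sand exceeds 100 at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(sites$group %in% c(0L, 1L))) {
    stop("group must be binary 0/1 (1 = treated)")
  }
  invisible(sites)
}

#' Validate a table of panel observations
#'
#' @param observations data.frame with one row per site x timepoint.
#' @param sites optional site table; when given, group-consistency of
#'   `treated_now` is checked (untreated sites never flagged treated).
#' @return The input, invisibly, after validation.
#' @export
validate_observations <- function(observations, sites = NULL) {
  missing <- setdiff(obs_columns(), names(observations))
  if (length(missing)) {
    stop("observation table is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(observations$cover < 0 | observations$cover > 100 |
                 observations$cover != round(observations$cover))
  if (length(bad)) {
    stop("cover must be an integer in [0, 100]; violated at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  dup <- duplicated(observations[, c("site_id", "time")])
  if (any(dup)) {
    stop("duplicate (site_id, time) at row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  }
  bad <- which(observations$time <= 0 & observations$treated_now != 0)
  if (length(bad)) {
    stop("treated_now must be 0 at and before the baseline timepoint; row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(sites)) {
    untreated <- sites$site_id[sites$group == 0L]
    bad <- which(observations$site_id %in% untreated & observations$treated_now != 0)
    if (length(bad)) {
      stop("treated_now must be 0 for untreated sites; row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  invisible(observations)
}

#' Read a site-by-year panel from CSV
#'
#' Reads a long CSV (one row per location x year; time-invariant site
#' covariates repeated on every row), validates it, and splits it into a site
#' table and an observation table. Sites without a baseline (`time == 0`) row
#' are rejected with a warning; remaining sites are kept.
#'
#' @param path path to a UTF-8, comma-separated CSV with a header row.
#' @param schema optional named character vector mapping canonical column
#'   names (names of the vector) to the file's column names, for files whose
#'   headers differ from the canonical ones.
#' @return A list with elements `sites` (one row per location) and
#'   `observations` (one row per location x year).
#' @export
load_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      file_col <- schema[[canon]]
      if (!file_col %in% names(raw)) {
        stop("schema maps '", canon, "' to missing file column '", file_col, "'")
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  required <- union(setdiff(site_columns(), "treatment_year"), obs_columns())
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("panel CSV is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"treatment_year" %in% names(raw)) raw$treatment_year <- NA_integer_
  raw$treatment_year <- as.integer(raw$treatment_year)

  has_baseline <- tapply(raw$time == 0, raw$site_id, any)
  drop_ids <- names(has_baseline)[!has_baseline]
  if (length(drop_ids)) {
    warning(length(drop_ids), " site(s) lack a time = 0 baseline row and were rejected")
    raw <- raw[!(as.character(raw$site_id) %in% drop_ids), , drop = FALSE]
  }
  if (!nrow(raw)) stop("no sites with a baseline row remain after filtering")

  site_cols <- site_columns()
  sites <- raw[!duplicated(raw$site_id), site_cols, drop = FALSE]
  rownames(sites) <- NULL
  observations <- raw[, obs_columns(), drop = FALSE]
  observations <- observations[order(observations$site_id, observations$time), , drop = FALSE]
  rownames(observations) <- NULL

  validate_sites(sites)
  validate_observations(observations, sites)
  log_info("load_panel: %d sites, %d observations (%d site(s) rejected)",
           nrow(sites), nrow(observations), length(drop_ids))
  list(sites = sites, observations = observations)
}

#' Write a site-by-year panel to CSV
#'
#' Inverse of [load_panel()]: joins the site table onto the observation table
#' and writes one long CSV. A write/read round trip reproduces the records
#' (integer covers exactly; floating covariates to full printed precision).
#'
#' @param sites,observations tables as returned by [load_panel()] or
#'   [simulate_landscape()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(sites, observations, path) {
  validate_sites(sites)
  validate_observations(observations, sites)
  merged <- merge(observations, sites, by = "site_id", sort = FALSE)
  merged <- merged[order(merged$site_id, merged$time),
                   union(obs_columns(), site_columns()), drop = FALSE]
  utils::write.csv(merged, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Standardization -------------------------------------------------------------

#' Center and scale covariates
#'
#' Centers each named covariate by its mean and scales by one standard
#' deviation, returning the transformed table plus a `standardization_record`
#' holding per-covariate centers and scales so the transform can be reapplied
#' (to new data or prediction settings) or inverted.
#'
#' Quadratic model terms downstream are squares of the standardized
#' variable (standardize-then-square), so linear and quadratic coefficients
#' live on comparable scales.
#'
#' @param data data.frame containing the covariates.
#' @param covariate_names character vector of numeric columns to standardize.
#' @return list with `data` (transformed) and `record`
#'   (a `standardization_record`).
#' @export
standardize_covariates <- function(data, covariate_names) {
  center <- numeric(0)
  scale <- numeric(0)
  for (nm in covariate_names) {
    x <- data[[nm]]
    if (is.null(x)) stop("covariate not found: ", nm)
    if (!is.numeric(x)) stop("covariate is not numeric: ", nm)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("zero-variance covariate: ", nm)
    m <- mean(x)
    data[[nm]] <- (x - m) / s
    center[nm] <- m
    scale[nm] <- s
  }
  record <- structure(list(center = center, scale = scale),
                      class = "standardization_record")
  list(data = data, record = record)
}

#' Apply a stored standardization to new data
#'
#' @param data data.frame with raw-scale covariates.
#' @param record a `standardization_record` from [standardize_covariates()].
#' @param strict error if a recorded covariate is absent (default TRUE).
#' @return data.frame with the recorded covariates standardized.
#' @export
apply_standardization <- function(data, record, strict = TRUE) {
  stopifnot(inherits(record, "standardization_record"))
  for (nm in names(record$center)) {
    if (is.null(data[[nm]])) {
      if (strict) stop("covariate not found: ", nm) else next
    }
    data[[nm]] <- (data[[nm]] - record$center[[nm]]) / record$scale[[nm]]
  }
  data
}

#' Invert a stored standardization
#'
#' @inheritParams apply_standardization
#' @return data.frame with the recorded covariates back on their raw scale.
#' @export
invert_standardization <- function(data, record, strict = TRUE) {
  stopifnot(inherits(record, "standardization_record"))
  for (nm in names(record$center)) {
    if (is.null(data[[nm]])) {
      if (strict) stop("covariate not found: ", nm) else next
    }
    data[[nm]] <- data[[nm]] * record$scale[[nm]] + record$center[[nm]]
  }
  data
}

#' @export
print.standardization_record <- function(x, ...) {
  cat("standardization record (", length(x$center), " covariates)\n", sep = "")
  print(data.frame(center = x$center, scale = x$scale))
  invisible(x)
}

#' Serialize / read a standardization record as JSON
#'
#' @param record a `standardization_record`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_standardization()` returns the record.
#' @export
write_standardization <- function(record, path) {
  stopifnot(inherits(record, "standardization_record"))
  jsonlite::write_json(list(center = as.list(record$center),
                            scale = as.list(record$scale)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_standardization
#' @export
read_standardization <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = unlist(x$center), scale = unlist(x$scale)),
            class = "standardization_record")
}

# Frames -----------------------------------------------------------------------

#' Build the estimation frames
#'
#' Constructs the three data frames the estimator ladder consumes:
#' \describe{
#'   \item{cross_section}{one row per site at `time == post_year`; feeds the
#'     difference-in-means, matched, and covariate-adjusted models.}
#'   \item{did_frame}{two rows per site (baseline year 0 and `post_year`)
#'     with a binary `time_post` indicator; feeds difference-in-differences.}
#'   \item{panel_frame}{`post_year + 1` rows per site (years 0..`post_year`)
#'     with categorical time-since-treatment (`time_f`) and the `treated_now`
#'     indicator; feeds the within-estimator panel regression.}
#' }
#' Sites missing any required timepoint are dropped with a logged count.
#' Observations with missing weather are dropped (complete-case analysis),
#' also logged.
#'
#' @param sites,observations tables as returned by [load_panel()].
#' @param post_year the post-treatment comparison year (integer in 1..10,
#'   default 10).
#' @return list of the three frames; attribute `dropped_sites` holds the
#'   number of sites removed.
#' @export
build_frames <- function(sites, observations, post_year = 10L) {
  stopifnot(post_year >= 1, post_year <= 10)
  validate_sites(sites)
  validate_observations(observations, sites)

  obs <- observations[observations$time >= 0 & observations$time <= post_year, , drop = FALSE]
  n_weather_na <- sum(is.na(obs$spring_precip) | is.na(obs$spring_temp))
  if (n_weather_na) {
    log_info("build_frames: dropping %d observation(s) with missing weather", n_weather_na)
    obs <- obs[!(is.na(obs$spring_precip) | is.na(obs$spring_temp)), , drop = FALSE]
  }

  required_times <- 0:post_year
  counts <- tapply(obs$time, obs$site_id, function(t) sum(required_times %in% t))
  keep_ids <- names(counts)[counts == length(required_times)]
  dropped <- nrow(sites) - length(keep_ids)
  if (dropped > 0) {
    log_info("build_frames: dropping %d site(s) missing required timepoints", dropped)
  }
  if (!length(keep_ids)) stop("no sites with complete timepoint coverage remain")

  sites_k <- sites[as.character(sites$site_id) %in% keep_ids, , drop = FALSE]
  obs_k <- obs[as.character(obs$site_id) %in% keep_ids, , drop = FALSE]

  join <- function(o) {
    out <- merge(o, sites_k, by = "site_id", sort = FALSE)
    out[order(out$site_id, out$time), , drop = FALSE]
  }

  cross_section <- join(obs_k[obs_k$time == post_year, , drop = FALSE])
  rownames(cross_section) <- NULL

  did_frame <- join(obs_k[obs_k$time %in% c(0L, post_year), , drop = FALSE])
  did_frame$time_post <- as.integer(did_frame$time == post_year)
  rownames(did_frame) <- NULL

  panel_frame <- join(obs_k)
  panel_frame$time_f <- factor(panel_frame$time, levels = required_times)
  rownames(panel_frame) <- NULL

  out <- list(cross_section = cross_section, did_frame = did_frame,
              panel_frame = panel_frame)
  attr(out, "post_year") <- as.integer(post_year)
  attr(out, "dropped_sites") <- dropped
  log_info("build_frames: cross_section %d, did_frame %d, panel_frame %d rows",
           nrow(cross_section), nrow(did_frame), nrow(panel_frame))
  out
}
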