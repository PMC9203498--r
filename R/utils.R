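# Internal helpers: keyed pseudo-random streams and logging.

# Derive a deterministic 32-bit seed from (seed, stream, index).
# Streams keep site-level draws independent of how many other sites exist:
# each site's (or fire's) draws come from its own substream, so enlarging a
# landscape appends draws instead of shifting existing ones.
keyed_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  base <- (as.double(seed) %% 1e6) * 10007
  key <- (base + as.double(stream) * 7919 + as.double(index) * 104729) %% 2147483647
  as.integer(key)
}

# Evaluate `expr` under a keyed seed without disturbing the caller's RNG state.
with_keyed_seed <- function(seed, stream, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(keyed_seed(seed, stream, index))
  expr
}

# Stage-level logging: row counts and dropped-record counts are reported via
# message() so callers (and tests) can silence or capture them.
log_info <- function(...) {
  message(sprintf(...))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Truncated normal by rejection-free clamping of quantiles (exact for the
# purpose of generating bounded covariates).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
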