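# Internal helpers shared across modules.

#' Physical half-life of iodine-123 in minutes
#'
#' Standard nuclide value (13.2235 h). Used as the default wherever decay
#' correction is applied.
#' @export
I123_HALF_LIFE_MIN <- 13.2235 * 60

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded helpers do not perturb each other.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

# Moment-matched log-normal parameters for a target arithmetic mean and SD.
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
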