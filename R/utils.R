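# Internal helpers shared across modules.

# Named seed streams: every stage of the pipeline draws from its own
# deterministic sub-seed so cohorts, expression matrices and permutations
# are independently reproducible from one master seed.
.stream_offsets <- c(
  cohort = 101L, ages = 211L, covariates = 307L,
  truth = 401L, expression = 503L, permutation = 601L
)

.stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  off <- .stream_offsets[[stream]]
  # keep the derived seed inside 32-bit integer range
  as.integer((abs(as.numeric(seed)) %% 2097143) * 1013 + off)
}

.assert_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Sample from a normal truncated to [a, b] via inverse-CDF; deterministic
# under the current RNG state.
.rtruncnorm <- function(n, mean, sd, a, b) {
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  u <- stats::runif(n, lo, hi)
  pmin(pmax(stats::qnorm(u, mean, sd), a), b)
}

# Mean of a normal(mu, sd) truncated to [a, b].
.truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  z <- stats::pnorm(be) - stats::pnorm(al)
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / z
}

# Location parameter so that the [a, b]-truncated normal has the target mean.
.truncnorm_location <- function(target, sd, a, b) {
  f <- function(mu) .truncnorm_mean(mu, sd, a, b) - target
  stats::uniroot(f, lower = a - 5 * sd, upper = b + 5 * sd,
                 tol = 1e-10)$root
}
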