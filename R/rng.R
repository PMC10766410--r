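# Seed plumbing shared by the simulators.
#
# Substreams are derived from one master seed by mixing in integer indices,
# so that enlarging a cohort (or adding a hormone) never reshuffles the
# random draws of earlier subjects.

# 2^31 - 1; all derived seeds stay below it so set.seed() receives a valid
# 32-bit integer.
.seed_modulus <- 2147483647

derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% .seed_modulus
  for (x in c(...)) {
    h <- (h * 69069 + as.numeric(x) + 1) %% .seed_modulus
  }
  as.integer(h)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Truncated-normal draws by inverse-CDF; sd = 0 degenerates to the mean
# (floored at `lower`).
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd <= 0) {
    return(rep(max(mean, lower), n))
  }
  p_lo <- pnorm(lower, mean, sd)
  u <- runif(n, p_lo, 1)
  pmax(qnorm(u, mean, sd), lower)
}

# Mean of a normal(mean, sd) truncated below at `lower`.
trunc_norm_mean <- function(mean, sd, lower) {
  if (sd <= 0) {
    return(max(mean, lower))
  }
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

# Lognormal multiplier with unit mean and coefficient of variation `cv`.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}
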