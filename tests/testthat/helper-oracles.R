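# Independent numerical oracles used across the suite.

# Matrix exponential by uniformization: P(t) = sum_k Pois(k; lambda t) B^k
# with B = I + Q/lambda. Independent of the package's Pade-based expm.
expm_unif <- function(Q, t, tol = 1e-14) {
  n <- nrow(Q)
  lambda <- max(-diag(Q))
  if (lambda == 0 || t == 0) return(diag(n))
  B <- diag(n) + Q / lambda
  mu <- lambda * t
  # Poisson weights by forward recursion
  kmax <- max(20, ceiling(mu + 12 * sqrt(mu)))
  P <- matrix(0, n, n)
  term <- diag(n)               # B^k, k = 0
  w <- exp(-mu)                 # Pois(0)
  P <- P + w * term
  for (k in 1:kmax) {
    term <- term %*% B
    w <- w * mu / k
    P <- P + w * term
    if (w < tol && k > mu) break
  }
  P
}

# Parameter set with the given baseline intensities, all others zero, all
# hazard ratios 1. Used for closed-form toy models.
toy_params <- function(...) {
  b <- stats::setNames(rep(0, 8),
                       c("nw_ow", "prog", "ow_nw", "regr",
                         "dm_nw", "dm_ow", "dm_ob1", "dm_ob23"))
  args <- list(...)
  b[names(args)] <- unlist(args)
  make_params(baseline = b)
}

# Random positive parameter set (seeded by the caller).
random_params <- function() {
  unpack_params(stats::rnorm(27, mean = log(0.05), sd = 1))
}

random_profile <- function() {
  covariate_profile(sample(c("M", "F"), 1),
                    sample(c(10, 30, 45, 60), 1),
                    sample(c(1980, 2000, 2010), 1))
}

# Small life table / cohort helpers for projection tests.
zero_mortality_lifetable <- function(years = 1990:2030) {
  make_synthetic_lifetable(alpha = 0, years = years)
}
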