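# Truncated-normal helpers used by the cohort generator.
#
# Sampling goes through the inverse CDF so that a Gaussian copula can impose
# wave-to-wave correlation while keeping each wave's marginal an exact
# truncated normal (the generator relies on this for exact effect
# calibration).

tnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  mu + sigma * (dnorm(a) - dnorm(b)) / z
}

# Quantile function of N(mu, sigma) truncated to [lo, hi].
qtnorm <- function(p, mu, sigma, lo, hi) {
  pa <- pnorm(lo, mu, sigma)
  pb <- pnorm(hi, mu, sigma)
  q <- qnorm(pa + p * (pb - pa), mu, sigma)
  pmin(pmax(q, lo), hi)
}

rtnorm <- function(n, mu, sigma, lo, hi) {
  qtnorm(runif(n), mu, sigma, lo, hi)
}

# Pre-truncation location shift delta such that the post-truncation mean of
# N(mu + delta, sigma) on [lo, hi] exceeds that of N(mu, sigma) by `target`.
tnorm_shift_for_delta <- function(mu, sigma, lo, hi, target) {
  if (abs(target) < .Machine$double.eps) return(0)
  base <- tnorm_mean(mu, sigma, lo, hi)
  f <- function(d) tnorm_mean(mu + d, sigma, lo, hi) - base - target
  # expand the bracket in the direction of the shift; the truncated mean is
  # monotone in the location but the formula degenerates deep in the tail
  s <- sign(target)
  step <- sigma
  cap <- 50 * ((hi - lo) + sigma)
  while (step < cap) {
    v <- f(s * step)
    if (!is.finite(v)) break
    if (v * s >= 0) {
      return(uniroot(f, lower = min(0, s * step), upper = max(0, s * step),
                     tol = 1e-10)$root)
    }
    step <- step * 2
  }
  stop("requested mean shift ", target, " is not achievable on [", lo, ", ",
       hi, "]")
}
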