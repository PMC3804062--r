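# Shared oracles and utilities for the test suite.

# Deterministic "expected-count" sample from a pmf: each support point
# replicated in proportion to its mass, giving a near-noise-free
# empirical distribution.
expected_count_sample <- function(pmf, total = 2e5) {
  rep(pmf$support, round(pmf$mass * total))
}

# One-sample Kolmogorov-Smirnov test against a discrete pmf with a
# parametric-bootstrap null (plain ks.test p-values are invalid under
# ties). Returns the Monte-Carlo p-value.
ks_test_discrete <- function(x, pmf, n_mc = 300) {
  cdf <- cumsum(pmf$mass) / sum(pmf$mass)
  stat <- function(v) {
    ec <- ecdf(v)(pmf$support)
    max(abs(ec - cdf))
  }
  d_obs <- stat(x)
  n <- length(x)
  d_null <- replicate(n_mc, stat(sample_pmf(pmf, n)))
  mean(d_null >= d_obs)
}

# Exact transient solution of the critical birth-death master equation on
# a truncated state space, via deSolve. States 0..k_max, started from one
# progenitor; time measured in drift units tau = r*lambda*t (so the
# per-cell event rate is 2 per unit tau).
master_equation_pmf <- function(tau, k_max = 200) {
  rhs <- function(t, p, parms) {
    k <- 0:k_max
    gain_dup <- c(0, (k[-1] - 1) * p[-length(p)])   # from k-1 by duplication
    gain_loss <- c(k[-1] * p[-1], 0)                # from k+1 by loss
    list(gain_dup + gain_loss - 2 * k * p)
  }
  p0 <- c(0, 1, rep(0, k_max - 1))
  out <- deSolve::ode(p0, c(0, tau), rhs, NULL, method = "lsoda",
                      atol = 1e-12, rtol = 1e-10)
  p <- out[2, -1]
  names(p) <- 0:k_max
  p
}
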