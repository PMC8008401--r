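# Monte-Carlo oracles used as independent cross-checks of the quadrature
# routes.  They simulate the defining random variables directly and never
# call the quadrature code they are checking.

# Pr{content of Xbar +/- cS >= P} by brute-force simulation of (Z, chi^2)
mc_coverage_confidence <- function(c, n, P, reps = 2e5, seed = 42) {
  set.seed(seed)
  nu <- n - 1
  z <- rnorm(reps)
  w <- sqrt(rchisq(reps, nu) / nu)
  k <- pnorm(z / sqrt(n) + c * w) - pnorm(z / sqrt(n) - c * w)
  p_hat <- mean(k >= P)
  list(p = p_hat, se = sqrt(p_hat * (1 - p_hat) / reps))
}

# Pr{Xbar +/- cS contains mu +/- z_(1+P)/2 sigma} by simulation
mc_central_coverage <- function(c, n, P, reps = 2e5, seed = 42) {
  set.seed(seed)
  nu <- n - 1
  zp <- qnorm((1 + P) / 2)
  z <- rnorm(reps)
  w <- sqrt(rchisq(reps, nu) / nu)
  p_hat <- mean(c * w >= zp + abs(z) / sqrt(n))
  list(p = p_hat, se = sqrt(p_hat * (1 - p_hat) / reps))
}

# Pr{U_[n-j+1] - U_[j] >= P} by simulating uniform order statistics
mc_np_coverage <- function(n, j, P, reps = 2e4, seed = 42) {
  set.seed(seed)
  hits <- vapply(seq_len(reps), function(i) {
    u <- sort(runif(n))
    (u[n - j + 1] - u[j]) >= P
  }, logical(1))
  p_hat <- mean(hits)
  list(p = p_hat, se = sqrt(p_hat * (1 - p_hat) / reps))
}
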