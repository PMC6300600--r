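# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct formula evaluation, brute-force
# enumeration, and dense-grid quadrature.

# Posterior mean of beta_1 for an S = 2 mixture by grid quadrature.
# Evaluates the (unnormalized) log posterior on an interior grid of beta_1
# values and normalizes by summation.
grid_posterior_mean_s2 <- function(counts, fmat, lambda, n_grid = 2001) {
  b1 <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  logpost <- vapply(b1, function(b) {
    p <- b * fmat[1, ] + (1 - b) * fmat[2, ]
    sum(counts * log(pmax(p, 1e-300))) +
      (lambda[1] - 1) * log(b) + (lambda[2] - 1) * log(1 - b)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  sum(b1 * w) / sum(w)
}

# Exact one-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled observations to group A (tie-free samples only).
enumerate_wilcox_p <- function(a, b, alternative = "less") {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  na <- length(a)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  if (alternative == "less") mean(u_all <= u_obs) else mean(u_all >= u_obs)
}

# Benjamini-Hochberg adjusted p-values by the min-over-tail step-up formula.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(pmin(sorted, 1))))
  adj
}

# Total-variation distance between two probability vectors.
tvd <- function(p, q) sum(abs(p - q)) / 2

# Multinomial log-pmf via the factorial formula (integer counts only).
factorial_multinom_logpmf <- function(counts, p) {
  log(factorial(sum(counts))) - sum(log(factorial(counts))) +
    sum(counts * log(p))
}

toy_profiles <- function() {
  tibble::tibble(surrogate = c("s1", "s2"), n_ind = 1L,
                 d1 = c(0.7, 0.1), d2 = c(0.2, 0.1),
                 d3 = c(0.05, 0.5), d4 = c(0.05, 0.3))
}
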