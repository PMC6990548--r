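# Independent oracles used across tests. These deliberately re-derive results
# by different routes than the package (direct recursion, brute-force
# quadrature, closed forms) and must stay independent of the code they check.

# Cox-de Boor recursion for a single x over a full (clamped) knot vector.
bspline_oracle <- function(x, knots, degree) {
  m <- length(knots) - degree - 1L
  B <- function(j, d) {
    if (d == 0L) {
      if (knots[j] <= x && x < knots[j + 1]) return(1)
      # close the final interval on the right
      if (x == knots[length(knots)] && knots[j] < knots[j + 1] &&
          knots[j + 1] == knots[length(knots)]) return(1)
      return(0)
    }
    a <- 0
    if (knots[j + d] > knots[j])
      a <- (x - knots[j]) / (knots[j + d] - knots[j]) * B(j, d - 1L)
    b <- 0
    if (knots[j + d + 1] > knots[j + 1])
      b <- (knots[j + d + 1] - x) / (knots[j + d + 1] - knots[j + 1]) *
        B(j + 1L, d - 1L)
    a + b
  }
  vapply(seq_len(m), function(j) B(j, degree), numeric(1))
}

# Dense 2-d grid quadrature of the exact posterior of a two-parameter
# Bernoulli-logit model with independent N(0, prior_var) priors.
logistic_grid_posterior <- function(X, y, prior_var = 1000, lim = 6,
                                    ngrid = 241) {
  b0 <- seq(-lim, lim, length.out = ngrid)
  b1 <- seq(-lim, lim, length.out = ngrid)
  grid <- as.matrix(expand.grid(b0 = b0, b1 = b1))
  eta <- X %*% t(grid)
  ll <- colSums(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  lp <- ll - (grid[, 1]^2 + grid[, 2]^2) / (2 * prior_var)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mu <- c(sum(w * grid[, 1]), sum(w * grid[, 2]))
  sdv <- sqrt(c(sum(w * grid[, 1]^2), sum(w * grid[, 2]^2)) - mu^2)
  list(mean = mu, sd = sdv)
}

# Bernoulli deviance computed directly.
deviance_oracle <- function(y, pi) {
  -2 * sum(y * log(pi) + (1 - y) * log(1 - pi))
}
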