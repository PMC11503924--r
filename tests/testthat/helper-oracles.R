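# Independent brute-force oracles, deliberately written from textbook
# formulas (loops and explicit inverses), never via the package's own code.

oracle_mae <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[i] - y[i])
  s / length(x)
}

# product-moment form: (n*sum(xy) - sum(x)sum(y)) / sqrt(...)
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# central-moment descriptive statistics with moment skewness and excess
# kurtosis
oracle_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  list(min = min(x), max = max(x), mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# generic regularized normal-equations solve via explicit inverse
oracle_ridge <- function(H, y, rp) {
  solve(t(H) %*% H + rp * diag(ncol(H))) %*% t(H) %*% y
}

# smooth wiggly series for wavelet fixtures
wiggle <- function(n, seed = 1) {
  set.seed(seed)
  sin(seq_len(n) / 15) + 0.5 * cos(seq_len(n) / 47) + rnorm(n, sd = 0.3)
}
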