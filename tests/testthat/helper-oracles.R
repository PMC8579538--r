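# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations (per-window fits, brute-force
# enumeration, projected-gradient QP) kept separate from the package code
# paths they check.

# Savitzky-Golay oracle: least-squares polynomial fit in each sliding
# window (in wavenumber units), derivative of the fitted polynomial
# evaluated at the point. Boundary windows are the first/last full window.
sg_oracle <- function(y, g, m = 9, p = 2, d = 2) {
  n <- length(g)
  h <- (m - 1) %/% 2
  res <- numeric(n)
  for (t in seq_len(n)) {
    win <- if (t <= h) 1:m else if (t > n - h) (n - m + 1):n else
      (t - h):(t + h)
    cf <- coef(stats::lm(y[win] ~ stats::poly(g[win], p, raw = TRUE)))
    k <- d:p
    res[t] <- sum(cf[k + 1] * factorial(k) / factorial(k - d) *
                    g[t]^(k - d))
  }
  res
}

# Brute-force lower convex envelope: the pointwise maximum over all lines
# through two data points that lie on or below every data point.
bf_lower_envelope <- function(x, y) {
  n <- length(x)
  env <- rep(-Inf, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sl <- (y[j] - y[i]) / (x[j] - x[i])
      line <- y[i] + sl * (x - x[i])
      if (all(y >= line - 1e-9)) env <- pmax(env, line)
    }
  }
  env
}

# Brute-force Mahalanobis classifier: explicit distance to every class
# mean under a pooled covariance.
mahalanobis_oracle <- function(scores, class_means, pooled_cov, classes) {
  Sinv <- solve(pooled_cov)
  apply(scores, 1, function(x) {
    d <- apply(class_means, 1, function(mu)
      t(x - mu) %*% Sinv %*% (x - mu))
    classes[which.min(d)]
  })
}

# Projected-gradient solver for the SVM dual (dense QP oracle):
#   min 1/2 a' Q a - e' a  s.t.  0 <= a <= C,  y' a = 0.
# Projection onto the box/hyperplane intersection by bisection.
qp_oracle <- function(K, y, C, iters = 20000) {
  Q <- K * outer(y, y)
  n <- length(y)
  proj <- function(a) {
    f <- function(l) sum(y * pmin(pmax(a - l * y, 0), C))
    lo <- -1e6; hi <- 1e6
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(a - ((lo + hi) / 2) * y, 0), C)
  }
  a <- rep(0, n)
  eta <- 1 / max(abs(eigen(Q, only.values = TRUE)$values))
  for (i in seq_len(iters)) a <- proj(a - eta * as.numeric(Q %*% a - 1))
  list(alpha = a,
       objective = as.numeric(0.5 * t(a) %*% Q %*% a - sum(a)))
}

# Kruskal-Wallis H via explicit rank sums (tie-corrected).
kw_oracle <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# small helpers ---------------------------------------------------------------

toy_grid <- function(n = 50, hi = 1800, step = 4) seq(hi, by = -step,
                                                      length.out = n)

# two well-separated Gaussian blobs in p dims
toy_blobs <- function(n_per = 30, p = 2, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}
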