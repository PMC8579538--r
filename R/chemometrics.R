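# PCA and PLS1 engines -------------------------------------------------------

#' Principal component analysis by singular value decomposition
#'
#' Fits a PCA on an (already centered) matrix. The decomposition is via
#' SVD for numerical stability; loadings carry a deterministic sign
#' convention (largest-magnitude element of each column positive) so
#' scores plots are reproducible across platforms.
#'
#' @param X numeric matrix, rows = samples; expected column-centered
#'   (a warning is issued if column means exceed 1e-8 in magnitude).
#' @param k number of components, `k <= min(nrow(X) - 1, ncol(X))`.
#' @return a `pca_model`: `mean` (the column means actually removed, zero
#'   when `X` is pre-centered), `loadings` (p x k, orthonormal), `scores`
#'   (n x k), `sdev`, `explained_variance_pct` (length k, percentages of
#'   the *total* variance), `total_variance`, `k`.
#' @export
fit_pca <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k > min(n - 1L, p)) {
    stop("fit_pca: k = ", k, " exceeds min(n-1, p) = ", min(n - 1L, p),
         call. = FALSE)
  }
  mu <- colMeans(X)
  if (max(abs(mu)) > 1e-8) {
    warning("fit_pca: X does not look centered (max |col mean| = ",
            format(max(abs(mu))), "); centering internally")
    X <- sweep(X, 2, mu)
  } else {
    mu <- rep(0, p)
  }
  s <- svd(X, nu = 0, nv = min(n, p))
  tol <- max(dim(X)) * .Machine$double.eps * s$d[1]
  rank <- sum(s$d > tol)
  if (k > rank) {
    warning("fit_pca: rank deficiency, truncating k from ", k, " to ", rank)
    k <- rank
  }
  V <- s$v[, seq_len(k), drop = FALSE]
  # sign convention
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- X %*% V
  vars <- s$d^2 / (n - 1)
  total <- sum(vars)
  structure(
    list(mean = mu, loadings = V, scores = scores,
         sdev = s$d[seq_len(k)] / sqrt(n - 1),
         explained_variance_pct = 100 * vars[seq_len(k)] / total,
         total_variance = total, k = k),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components, %.1f%% variance explained\n",
              x$k, sum(x$explained_variance_pct)))
  invisible(x)
}

#' Project new data onto a fitted PCA
#'
#' @param m a `pca_model`.
#' @param X_new matrix with the same number of columns as the training data;
#'   centered by the model's mean before projection.
#' @return scores matrix, `nrow(X_new) x m$k`.
#' @export
project_pca <- function(m, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != nrow(m$loadings)) {
    stop("project_pca: X_new has ", ncol(X_new), " columns, model expects ",
         nrow(m$loadings), call. = FALSE)
  }
  sweep(X_new, 2, m$mean) %*% m$loadings
}

# PLS1 (NIPALS) --------------------------------------------------------------

#' Fit a univariate-response PLS regression (PLS1, NIPALS)
#'
#' Sequentially extracts latent variables maximising covariance between
#' X-scores and the (centered) response. With `n_lv = rank(X)` the
#' in-sample fit coincides with least squares on the column space of X.
#'
#' @param X predictor matrix (rows = samples); centered internally.
#' @param y numeric response vector.
#' @param n_lv number of latent variables.
#' @param cv optional fold assignment (integer vector, as from
#'   [venetian_blinds()]); when given, `cv_rmse_per_lv` holds the
#'   cross-validated RMSE for 1..n_lv latent variables.
#' @return a `pls1_model`: weights, loadings, `regression_vector` (for the
#'   centered problem), `x_mean`, `y_mean`, `n_lv`, `cv_rmse_per_lv`.
#' @export
fit_pls1 <- function(X, y, n_lv, cv = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("fit_pls1: length(y) != nrow(X)",
                                 call. = FALSE)
  if (stats::sd(y) == 0) stop("fit_pls1: constant response", call. = FALSE)
  fit_core <- function(X, y, a) {
    x_mean <- colMeans(X); y_mean <- mean(y)
    E <- sweep(X, 2, x_mean); f <- y - y_mean
    p <- ncol(X)
    W <- matrix(0, p, a); P <- matrix(0, p, a); q <- numeric(a)
    Tm <- matrix(0, nrow(X), a)
    for (j in seq_len(a)) {
      w <- crossprod(E, f)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) { a <- j - 1L; break }
      w <- w / nw
      t <- E %*% w
      tt <- sum(t^2)
      pj <- crossprod(E, t) / tt
      qj <- sum(f * t) / tt
      E <- E - t %*% t(pj)
      f <- f - qj * t
      W[, j] <- w; P[, j] <- pj; q[j] <- qj; Tm[, j] <- t
    }
    if (a == 0L) stop("fit_pls1: X carries no covariance with y",
                      call. = FALSE)
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    q <- q[seq_len(a)]
    # regression vector for centered X: b = W (P'W)^-1 q
    B <- W %*% solve(t(P) %*% W, q)
    list(x_weights = W, x_loadings = P, y_loadings = q,
         regression_vector = as.numeric(B), x_mean = x_mean, y_mean = y_mean,
         n_lv = a, scores = Tm[, seq_len(a), drop = FALSE])
  }
  m <- fit_core(X, y, n_lv)
  cv_rmse <- NULL
  if (!is.null(cv)) {
    cv_rmse <- numeric(m$n_lv)
    press <- matrix(0, length(unique(cv)), m$n_lv)
    for (fi in seq_along(sort(unique(cv)))) {
      f <- sort(unique(cv))[fi]
      tr <- cv != f; te <- !tr
      mf <- fit_core(X[tr, , drop = FALSE], y[tr], m$n_lv)
      for (a in seq_len(m$n_lv)) {
        aa <- min(a, mf$n_lv)
        pred <- predict_pls1(truncate_pls(mf, aa), X[te, , drop = FALSE])
        press[fi, a] <- sum((y[te] - pred)^2)
      }
    }
    cv_rmse <- sqrt(colSums(press) / length(y))
  }
  m$cv_rmse_per_lv <- cv_rmse
  class(m) <- "pls1_model"
  m
}

truncate_pls <- function(m, a) {
  W <- m$x_weights[, seq_len(a), drop = FALSE]
  P <- m$x_loadings[, seq_len(a), drop = FALSE]
  q <- m$y_loadings[seq_len(a)]
  m$regression_vector <- as.numeric(W %*% solve(t(P) %*% W, q))
  m$n_lv <- a
  m
}

#' Predict from a PLS1 model
#'
#' @param m a `pls1_model`.
#' @param X_new predictor matrix.
#' @return numeric vector of predictions.
#' @export
predict_pls1 <- function(m, X_new) {
  X_new <- as.matrix(X_new)
  as.numeric(sweep(X_new, 2, m$x_mean) %*% m$regression_vector + m$y_mean)
}

#' Choose the number of PLS latent variables by cross-validation
#'
#' Minimises cross-validated RMSE over 1..`max_lv`; exact ties (within
#' 1e-12 relative) are broken toward fewer latent variables.
#'
#' @param X,y as in [fit_pls1()].
#' @param max_lv largest model to consider.
#' @param cv fold assignment (default: 10-split venetian blinds).
#' @return integer number of latent variables.
#' @export
select_n_lv <- function(X, y, max_lv, cv = venetian_blinds(nrow(X), 10)) {
  m <- fit_pls1(X, y, max_lv, cv = cv)
  r <- m$cv_rmse_per_lv
  best <- min(r)
  which(r <= best * (1 + 1e-12))[1]
}
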