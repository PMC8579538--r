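# PCA-LDA and RBF-SVM classifiers -------------------------------------------

#' Fit a PCA-LDA classifier
#'
#' Principal component scores are used as input variables for linear
#' discriminant analysis; classification is by minimum Mahalanobis
#' distance to the class means under the pooled within-class covariance,
#' with equal priors (the sampling design is near-balanced). Canonical
#' directions for scores plots come from the between/within generalized
#' eigenproblem.
#'
#' @param X_train centered matrix (rows = spectra).
#' @param labels class labels, length `nrow(X_train)`; class order is the
#'   sorted unique label set.
#' @param n_pcs number of principal components retained
#'   (`>= n_classes - 1`).
#' @param ridge_eps relative ridge added to the pooled covariance only
#'   when its condition number exceeds 1e10 (with a warning).
#' @return a `pca_lda_model`.
#' @export
fit_pca_lda <- function(X_train, labels, n_pcs = 10, ridge_eps = 1e-8) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("fit_pca_lda: need >= 2 classes",
                                call. = FALSE)
  if (any(table(labels) < 2)) stop("fit_pca_lda: every class needs >= 2 rows",
                                   call. = FALSE)
  if (n_pcs < length(classes) - 1) {
    stop("fit_pca_lda: n_pcs must be >= n_classes - 1", call. = FALSE)
  }
  pca <- fit_pca(X_train, n_pcs)
  S <- pca$scores
  k <- ncol(S)
  n <- nrow(S)
  class_means <- t(vapply(classes, function(cl)
    colMeans(S[labels == cl, , drop = FALSE]), numeric(k)))
  # pooled within-class covariance (n - g denominator)
  W <- matrix(0, k, k)
  for (cl in classes) {
    Sc <- S[labels == cl, , drop = FALSE]
    Sc <- sweep(Sc, 2, colMeans(Sc))
    W <- W + crossprod(Sc)
  }
  W <- W / (n - length(classes))
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > 1e10) {
    warning("fit_pca_lda: ill-conditioned pooled covariance, adding ridge ",
            format(ridge_eps))
    W <- W + diag(ridge_eps * sum(diag(W)) / k, k)
  }
  W_inv <- solve(W)
  # between-class scatter (equal priors over classes)
  gm <- colMeans(class_means)
  B <- matrix(0, k, k)
  for (i in seq_along(classes)) {
    d <- class_means[i, ] - gm
    B <- B + tcrossprod(d)
  }
  B <- B / length(classes)
  # canonical directions: eigenvectors of W^-1 B via symmetric whitening
  Wc <- chol(W)
  M <- solve(t(Wc), t(solve(t(Wc), B)))  # W^-1/2' B W^-1/2 (symmetric)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ncan <- min(length(classes) - 1L, k)
  canon <- backsolve(Wc, eg$vectors[, seq_len(ncan), drop = FALSE])
  for (j in seq_len(ncan)) {
    i <- which.max(abs(canon[, j]))
    if (canon[i, j] < 0) canon[, j] <- -canon[, j]
  }
  structure(
    list(pca = pca, classes = classes, class_means = class_means,
         pooled_cov = W, pooled_cov_inv = W_inv,
         canonical_directions = canon, canonical_eigenvalues =
           eg$values[seq_len(ncan)],
         priors = rep(1 / length(classes), length(classes))),
    class = "pca_lda_model"
  )
}

#' Predict with a PCA-LDA model
#'
#' @param m a `pca_lda_model`.
#' @param X matrix in the training (centered) spectral space.
#' @return list with `labels` (minimum-Mahalanobis class; ties go to the
#'   first class in sorted label order), `canonical_scores`, and
#'   `distances` (n x n_classes squared Mahalanobis distances).
#' @export
predict_pca_lda <- function(m, X) {
  S <- project_pca(m$pca, X)
  ncl <- length(m$classes)
  D <- matrix(0, nrow(S), ncl)
  for (i in seq_len(ncl)) {
    d <- sweep(S, 2, m$class_means[i, ])
    D[, i] <- rowSums((d %*% m$pooled_cov_inv) * d)
  }
  idx <- apply(D, 1, which.min)  # which.min takes the first (tie rule)
  list(labels = m$classes[idx],
       canonical_scores = S %*% m$canonical_directions,
       distances = D)
}

# RBF SVM --------------------------------------------------------------------

#' Fit a soft-margin SVM with RBF kernel
#'
#' One-vs-one multiclass scheme; each binary subproblem's dual is solved
#' by sequential minimal optimisation with maximal-violating-pair working
#' set selection (deterministic in the input row order). The kernel is
#' `K(x, z) = exp(-gamma * ||x - z||^2)`. Class probabilities use Platt
#' sigmoids fitted on cross-validated decision values, combined by
#' pairwise coupling.
#'
#' @param X_train matrix of training spectra (rows = samples).
#' @param labels class labels; class order is the sorted unique set.
#' @param cost soft-margin cost C (> 0).
#' @param gamma RBF width parameter (> 0).
#' @param probability fit Platt sigmoids for probability output?
#' @param platt_folds internal folds for the cross-validated decision
#'   values the sigmoids are fitted on.
#' @param tol SMO stopping tolerance on the KKT violation.
#' @param max_iter iteration cap per binary subproblem; exceeding it is an
#'   error with diagnostics.
#' @return an `svm_rbf_model` storing unique support vectors, per-pair dual
#'   coefficients and intercepts, Platt parameters and `n_sv`.
#' @export
fit_svm_rbf <- function(X_train, labels, cost = 10, gamma = 3.16,
                        probability = TRUE, platt_folds = 3, tol = 1e-4,
                        max_iter = NULL) {
  X_train <- as.matrix(X_train)
  labels <- as.character(labels)
  stopifnot(cost > 0, gamma > 0)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("fit_svm_rbf: need >= 2 classes",
                                call. = FALSE)
  if (is.null(max_iter)) max_iter <- max(2e5L, 1000L * nrow(X_train))
  K_full <- rbf_kernel(X_train, X_train, gamma)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  sv_mask <- rep(FALSE, nrow(X_train))
  fits <- vector("list", length(pairs))
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    idx <- which(labels %in% pr)
    y <- ifelse(labels[idx] == pr[1], 1, -1)
    sol <- smo_solve(K_full[idx, idx, drop = FALSE], y, cost, tol, max_iter)
    if (!sol$converged) {
      stop("fit_svm_rbf: SMO did not converge for pair ", pr[1], "/", pr[2],
           " after ", sol$iterations, " iterations (C=", cost, ", gamma=",
           gamma, "); raise max_iter or loosen tol", call. = FALSE)
    }
    sv_local <- which(sol$alpha > 1e-8 * cost)
    sv_mask[idx[sv_local]] <- TRUE
    fits[[pi]] <- list(
      classes = pr, train_idx = idx[sv_local],
      coef = sol$alpha[sv_local] * y[sv_local], rho = sol$rho,
      objective = sol$objective, iterations = sol$iterations)
  }
  sv_idx <- which(sv_mask)
  remap <- integer(nrow(X_train)); remap[sv_idx] <- seq_along(sv_idx)
  for (pi in seq_along(fits)) {
    fits[[pi]]$sv_rows <- remap[fits[[pi]]$train_idx]
  }
  m <- structure(
    list(classes = classes, cost = cost, gamma = gamma,
         support_vectors = X_train[sv_idx, , drop = FALSE],
         sv_class_labels = labels[sv_idx], sv_train_idx = sv_idx,
         n_sv = length(sv_idx), pair_fits = fits, platt_params = NULL,
         tol = tol),
    class = "svm_rbf_model"
  )
  if (probability) {
    m$platt_params <- fit_platt_params(X_train, labels, m, platt_folds,
                                       max_iter)
  }
  m
}

#' @export
print.svm_rbf_model <- function(x, ...) {
  cat(sprintf("<svm_rbf_model> %d classes, cost=%g, gamma=%g, N_SV=%d\n",
              length(x$classes), x$cost, x$gamma, x$n_sv))
  invisible(x)
}

# decision values of all pairs for new data; returns n x n_pairs matrix
svm_decision_values <- function(m, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(m$support_vectors)) {
    stop("predict_svm: dimension mismatch", call. = FALSE)
  }
  Kn <- rbf_kernel(X, m$support_vectors, m$gamma)
  D <- matrix(0, nrow(X), length(m$pair_fits))
  for (pi in seq_along(m$pair_fits)) {
    f <- m$pair_fits[[pi]]
    D[, pi] <- Kn[, f$sv_rows, drop = FALSE] %*% f$coef - f$rho
  }
  D
}

# Platt sigmoid fit (Newton with backtracking; Lin, Weng & Platt targets).
platt_fit <- function(dec, y_pos) {
  n <- length(dec)
  np <- sum(y_pos); nn <- n - np
  t <- ifelse(y_pos, (np + 1) / (np + 2), 1 / (nn + 2))
  A <- 0; B <- log((nn + 1) / (np + 1))
  fval <- function(A, B) {
    fApB <- dec * A + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  F0 <- fval(A, B)
  for (it in 1:100) {
    fApB <- dec * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(dec * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(dec^2 * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(dec * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= 1e-10) {
      nA <- A + step * dA; nB <- B + step * dB
      Fn <- fval(nA, nB)
      if (Fn < F0 + 1e-4 * step * gd) { A <- nA; B <- nB; F0 <- Fn; break }
      step <- step / 2
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)
}

# cross-validated decision values per pair, then sigmoid fit
fit_platt_params <- function(X, labels, m, folds, max_iter) {
  out <- vector("list", length(m$pair_fits))
  for (pi in seq_along(m$pair_fits)) {
    pr <- m$pair_fits[[pi]]$classes
    idx <- which(labels %in% pr)
    Xp <- X[idx, , drop = FALSE]
    y <- ifelse(labels[idx] == pr[1], 1, -1)
    n <- length(idx)
    fold <- venetian_blinds(n, min(folds, n))
    dec <- numeric(n)
    Kp <- rbf_kernel(Xp, Xp, m$gamma)
    for (f in sort(unique(fold))) {
      tr <- which(fold != f); te <- which(fold == f)
      sol <- smo_solve(Kp[tr, tr, drop = FALSE], y[tr], m$cost, m$tol,
                       max_iter)
      coef <- sol$alpha * y[tr]
      dec[te] <- Kp[te, tr, drop = FALSE] %*% coef - sol$rho
    }
    out[[pi]] <- platt_fit(dec, y > 0)
  }
  out
}

# pairwise coupling of per-pair probabilities (Wu, Lin & Weng 2004,
# second method, as used by the common SVM libraries)
couple_probabilities <- function(R) {
  k <- nrow(R)
  Q <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        s <- 0
        for (l in seq_len(k)) if (l != i) s <- s + R[l, i]^2
        Q[i, i] <- s
      } else {
        Q[i, j] <- -R[j, i] * R[i, j]
      }
    }
  }
  p <- rep(1 / k, k)
  Qp <- Q %*% p
  pQp <- as.numeric(t(p) %*% Qp)
  for (it in 1:200) {
    max_err <- max(abs(Qp - pQp))
    if (max_err < 1e-10) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p / sum(p)
}

#' Predict with an RBF SVM
#'
#' Labels come from one-vs-one majority voting (ties broken by summed
#' decision values); probabilities from per-pair Platt sigmoids combined
#' with pairwise coupling (rows sum to 1).
#'
#' @param m an `svm_rbf_model`.
#' @param X matrix of spectra in the training space.
#' @return list with `labels`, `probabilities` (n x n_classes, or `NULL`
#'   when the model was fitted without `probability`), and `decision_values`
#'   (n x n_pairs).
#' @export
predict_svm <- function(m, X) {
  D <- svm_decision_values(m, X)
  n <- nrow(D)
  ncl <- length(m$classes)
  votes <- matrix(0, n, ncl)
  decsum <- matrix(0, n, ncl)
  for (pi in seq_along(m$pair_fits)) {
    pr <- m$pair_fits[[pi]]$classes
    ia <- match(pr[1], m$classes); ib <- match(pr[2], m$classes)
    pos <- D[, pi] > 0
    votes[, ia] <- votes[, ia] + pos
    votes[, ib] <- votes[, ib] + !pos
    decsum[, ia] <- decsum[, ia] + D[, pi]
    decsum[, ib] <- decsum[, ib] - D[, pi]
  }
  lab_idx <- vapply(seq_len(n), function(i) {
    w <- which(votes[i, ] == max(votes[i, ]))
    if (length(w) > 1) w <- w[which.max(decsum[i, w])]
    w[1]
  }, integer(1))
  prob <- NULL
  if (!is.null(m$platt_params)) {
    prob <- matrix(0, n, ncl, dimnames = list(NULL, m$classes))
    for (i in seq_len(n)) {
      R <- matrix(1 / ncl, ncl, ncl)
      for (pi in seq_along(m$pair_fits)) {
        pr <- m$pair_fits[[pi]]$classes
        ia <- match(pr[1], m$classes); ib <- match(pr[2], m$classes)
        ab <- m$platt_params[[pi]]
        f <- ab["A"] * D[i, pi] + ab["B"]
        r <- if (f >= 0) exp(-f) / (1 + exp(-f)) else 1 / (1 + exp(f))
        r <- min(max(r, 1e-7), 1 - 1e-7)
        R[ia, ib] <- r
        R[ib, ia] <- 1 - r
      }
      prob[i, ] <- couple_probabilities(R)
    }
  }
  list(labels = m$classes[lab_idx], probabilities = prob,
       decision_values = D)
}

#' Tune SVM cost and gamma on a grid by venetian-blinds cross-validation
#'
#' Exhaustive grid search maximising CV accuracy; ties are broken toward
#' smaller cost, then smaller gamma.
#'
#' @param X,labels training data.
#' @param cost_grid,gamma_grid numeric candidate vectors.
#' @param cv fold assignment (default 10-split venetian blinds).
#' @param ... forwarded to [fit_svm_rbf()] (probability is forced off
#'   during the search).
#' @return list with `cost`, `gamma`, `cv_accuracy` and the full
#'   `grid` data.frame.
#' @export
tune_svm <- function(X, labels, cost_grid, gamma_grid,
                     cv = venetian_blinds(nrow(X), 10), ...) {
  stopifnot(length(cost_grid) >= 1, length(gamma_grid) >= 1)
  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  grid$cv_accuracy <- NA_real_
  labels <- as.character(labels)
  for (gi in seq_len(nrow(grid))) {
    correct <- 0
    for (f in sort(unique(cv))) {
      tr <- cv != f
      m <- fit_svm_rbf(X[tr, , drop = FALSE], labels[tr],
                       cost = grid$cost[gi], gamma = grid$gamma[gi],
                       probability = FALSE, ...)
      pred <- predict_svm(m, X[!tr, , drop = FALSE])$labels
      correct <- correct + sum(pred == labels[!tr])
    }
    grid$cv_accuracy[gi] <- correct / length(labels)
  }
  best <- which(grid$cv_accuracy >= max(grid$cv_accuracy) - 1e-12)
  # grid is sorted by (gamma outer, cost inner); re-sort ties by cost, gamma
  best <- best[order(grid$cost[best], grid$gamma[best])][1]
  list(cost = grid$cost[best], gamma = grid$gamma[best],
       cv_accuracy = grid$cv_accuracy[best], grid = grid)
}
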