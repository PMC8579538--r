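test_that("PCA-LDA separates well-separated blobs and is chance-level without signal", {
  tb <- toy_blobs(n_per = 50, p = 4, sep = 10, seed = 21)
  X <- scale(tb$X, scale = FALSE)
  m <- fit_pca_lda(X, tb$y, n_pcs = 3)
  expect_equal(mean(predict_pca_lda(m, X)$labels == tb$y), 1)
  # no signal: equal means, identity covariance
  set.seed(22)
  X0 <- scale(matrix(rnorm(300 * 4), 300, 4), scale = FALSE)
  y0 <- rep(c("a", "b"), 150)
  m0 <- fit_pca_lda(X0, y0, n_pcs = 3)
  acc <- mean(predict_pca_lda(m0, X0)$labels == y0)
  se <- sqrt(0.25 / 300)
  expect_lt(abs(acc - 0.5), 3 * se + 0.03)  # small optimism from fitting
})

test_that("PCA-LDA predictions equal the brute-force Mahalanobis oracle", {
  set.seed(23)
  n <- 15
  X <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2, 2), n, 2),
             matrix(rnorm(n * 2, c(0, 4)), n, 2))
  y <- rep(c("a", "b", "c"), each = n)
  X <- scale(X, scale = FALSE)
  m <- fit_pca_lda(X, y, n_pcs = 2)
  pred <- predict_pca_lda(m, X)
  oracle <- mahalanobis_oracle(project_pca(m$pca, X), m$class_means,
                               m$pooled_cov, m$classes)
  expect_identical(pred$labels, unname(oracle))
  # canonical scores have n_classes - 1 columns
  expect_equal(ncol(pred$canonical_scores), 2)
})

test_that("PCA-LDA tie-break, class-mean classification and consistency", {
  set.seed(24)
  X <- rbind(matrix(rnorm(20, -3, 0.5), 10, 2),
             matrix(rnorm(20, 3, 0.5), 10, 2))
  y <- rep(c("left", "right"), each = 10)
  X <- scale(X, scale = FALSE)
  m <- fit_pca_lda(X, y, n_pcs = 2)
  # a point exactly at a class mean (mapped back to input space) is classed there
  back <- m$class_means %*% t(m$pca$loadings)
  at_mean <- predict_pca_lda(m, back)
  expect_identical(at_mean$labels, m$classes)
  # equidistant point: exact midpoint -> first class in sorted label order
  mid <- matrix(colMeans(back), 1)
  expect_identical(predict_pca_lda(m, mid)$labels, m$classes[1])
  expect_error(fit_pca_lda(X, y, n_pcs = 0), "n_pcs")
})

test_that("LDA predictions survive a common affine rescaling of the input", {
  set.seed(25)
  tb <- toy_blobs(n_per = 25, p = 3, sep = 3, seed = 25)
  X <- scale(tb$X, scale = FALSE)
  m1 <- fit_pca_lda(X, tb$y, n_pcs = 3)
  m2 <- fit_pca_lda(X * 7.3, tb$y, n_pcs = 3)
  Xn <- matrix(rnorm(60), 20, 3)
  expect_identical(predict_pca_lda(m1, Xn)$labels,
                   predict_pca_lda(m2, Xn * 7.3)$labels)
})

test_that("SVM: separable KKT conditions and XOR non-linear separability", {
  tb <- toy_blobs(n_per = 20, p = 2, sep = 8, seed = 26)
  m <- fit_svm_rbf(tb$X, tb$y, cost = 1000, gamma = 0.5,
                   probability = FALSE, tol = 1e-6)
  pred <- predict_svm(m, tb$X)
  expect_equal(mean(pred$labels == tb$y), 1)
  # free SVs (0 < |alpha| < C) sit on the margin: decision value +/- 1
  f <- m$pair_fits[[1]]
  dv <- pred$decision_values[m$sv_train_idx[f$sv_rows], 1]
  free <- abs(f$coef) < 1000 * (1 - 1e-6)
  expect_lt(max(abs(abs(dv[free]) - 1)), 1e-3)
  # every dual coefficient magnitude <= C
  expect_lte(max(abs(f$coef)), 1000 + 1e-9)
  # XOR
  set.seed(27)
  Xx <- cbind(rep(c(1, 1, -1, -1), 25), rep(c(1, -1, 1, -1), 25)) +
    matrix(rnorm(200, sd = 0.2), 100, 2)
  yx <- ifelse(Xx[, 1] * Xx[, 2] > 0, "same", "diff")
  mx <- fit_svm_rbf(Xx, yx, cost = 10, gamma = 1, probability = FALSE)
  expect_equal(mean(predict_svm(mx, Xx)$labels == yx), 1)
})

test_that("SMO dual objective matches the dense QP oracle on 30-point problems", {
  set.seed(28)
  X <- matrix(rnorm(60), 30, 2)
  y <- ifelse(X[, 1] + X[, 2] + rnorm(30, 0, 0.5) > 0, "p", "n")
  ysgn <- ifelse(y == "n", 1, -1)  # first sorted class is positive
  K <- rbf_kernel(X, X, 0.5)
  or <- qp_oracle(K, ysgn, C = 10, iters = 12000)
  m <- fit_svm_rbf(X, y, cost = 10, gamma = 0.5, probability = FALSE,
                   tol = 1e-6)
  expect_lt(abs(m$pair_fits[[1]]$objective - or$objective) /
              abs(or$objective), 1e-4)
})

test_that("the decision function depends on the data only through its SVs", {
  set.seed(29)
  tb <- toy_blobs(n_per = 40, p = 2, sep = 5, seed = 29)
  m <- fit_svm_rbf(tb$X, tb$y, cost = 10, gamma = 0.5, probability = FALSE,
                   tol = 1e-8)
  keep <- m$sv_train_idx
  m2 <- fit_svm_rbf(tb$X[keep, , drop = FALSE], tb$y[keep], cost = 10,
                    gamma = 0.5, probability = FALSE, tol = 1e-8)
  Xg <- as.matrix(expand.grid(seq(-2, 7, length.out = 8),
                              seq(-2, 7, length.out = 8)))
  d1 <- predict_svm(m, Xg)$decision_values
  d2 <- predict_svm(m2, Xg)$decision_values
  expect_lt(max(abs(d1 - d2)), 1e-6)
})

test_that("probabilities are coherent and consistent with voting", {
  set.seed(30)
  n <- 30
  X <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, 6), rnorm(n, 6)),
             cbind(rnorm(n, 6), rnorm(n, -6)))
  y <- rep(c("a", "b", "c"), each = n)
  m <- fit_svm_rbf(X, y, cost = 10, gamma = 0.5)
  set.seed(31)
  Xt <- rbind(X, matrix(rnorm(40, 2), 20, 2), matrix(50, 2, 2))
  pr <- predict_svm(m, Xt)
  expect_equal(rowSums(pr$probabilities), rep(1, nrow(Xt)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(pr$probabilities >= 0))
  agree <- mean(m$classes[apply(pr$probabilities, 1, which.max)] ==
                  pr$labels)
  expect_gte(agree, 0.95)
  # training points of this separable toy: true-class probability > 0.5
  frac <- mean(pr$probabilities[cbind(1:(3 * n), match(y, m$classes))] >
                 0.5)
  expect_gte(frac, 0.95)
})

test_that("gamma -> 0 approaches a linear-like ordering on a fixed toy", {
  set.seed(32)
  X <- matrix(c(-2, -1, 1, 2), 4, 1)
  y <- c("n", "n", "p", "p")
  dec_at <- function(g) {
    m <- fit_svm_rbf(X, y, cost = 100, gamma = g, probability = FALSE,
                     tol = 1e-6)
    d <- predict_svm(m, matrix(seq(-2, 2, 0.5), ncol = 1))$decision_values
    d[, 1]
  }
  for (g in c(0.1, 0.01, 0.001)) {
    # decision should be monotone along the 1-D feature
    expect_true(all(diff(dec_at(g)) < 1e-8) || all(diff(dec_at(g)) > -1e-8))
  }
})

test_that("tune_svm searches the grid exhaustively with deterministic ties", {
  set.seed(33)
  tb <- toy_blobs(n_per = 30, p = 2, sep = 6, seed = 33)
  one <- tune_svm(tb$X, tb$y, cost_grid = 10, gamma_grid = 0.5)
  expect_equal(one$cost, 10)
  expect_equal(one$gamma, 0.5)
  tn <- tune_svm(tb$X, tb$y, cost_grid = c(0.1, 10),
                 gamma_grid = c(0.05, 0.5), cv = venetian_blinds(60, 5))
  # chosen pair attains the maximum of the full (independently stored) grid
  expect_equal(tn$cv_accuracy, max(tn$grid$cv_accuracy))
  best_rows <- tn$grid[tn$grid$cv_accuracy >= tn$cv_accuracy - 1e-12, ]
  expect_equal(tn$cost, min(best_rows$cost))
  # the published operating point (C = 10, gamma = 3.16) is expressible on
  # a standard half-decade log grid
  grid <- round(10^seq(-1, 2, 0.5), 2)
  expect_true(10 %in% grid && 3.16 %in% grid)
})
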