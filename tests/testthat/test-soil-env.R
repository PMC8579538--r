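test_that("autoscaling centers, scales and rejects constant columns", {
  two <- data.frame(site = c("A", "B"), x = c(1, 3), y = c(10, 0))
  sc <- autoscale(two)
  expect_equal(sc$X[, "x"], c(-1, 1) / sqrt(2), ignore_attr = TRUE)
  expect_equal(sc$X[, "y"], c(1, -1) / sqrt(2), ignore_attr = TRUE)
  set.seed(61)
  tab <- data.frame(a = rnorm(20, 5, 2), b = runif(20, 0, 100))
  sc2 <- autoscale(tab)
  expect_lt(max(abs(colMeans(sc2$X))), 1e-12)
  expect_equal(apply(sc2$X, 2, sd), c(1, 1), ignore_attr = TRUE)
  # already standardized -> unchanged
  std <- as.data.frame(scale(tab))
  expect_equal(autoscale(std)$X, as.matrix(std), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(autoscale(data.frame(a = rep(1, 5), b = rnorm(5))),
               "constant column")
})

test_that("autoscaled PCA is invariant to positive affine unit changes", {
  set.seed(62)
  tab <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  p1 <- fit_pca(autoscale(tab)$X, 2)
  tab2 <- data.frame(a = 1000 * tab$a + 5, b = tab$b / 7, c = tab$c + 100)
  p2 <- fit_pca(autoscale(tab2)$X, 2)
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-8)
})

test_that("Hotelling T2 flags a planted extreme row and spares clean data", {
  set.seed(63)
  clean <- data.frame(matrix(rnorm(20 * 4), 20, 4))
  planted <- rbind(clean, data.frame(matrix(10, 1, 4)))
  res <- soil_pca_with_outliers(planted, k = 2, t2_alpha = 0.05)
  expect_true(res$outliers[21])
  expect_equal(sum(res$outliers), 1)
  expect_false(is.null(res$pca_refit))
  # homogeneous data: false positives bounded (binomial 95% over seeds)
  fp <- vapply(1:10, function(s) {
    set.seed(400 + s)
    sum(soil_pca_with_outliers(data.frame(matrix(rnorm(80), 20, 4)),
                               k = 2)$outliers)
  }, numeric(1))
  # 0.05 x 20 rows x 10 seeds = 10 expected; 95% binomial upper bound
  expect_lte(sum(fp), qbinom(0.975, 200, 0.05))
  # rank-2 synthetic data is fully explained by 2 components
  t1 <- rnorm(15); t2 <- rnorm(15)
  r2 <- data.frame(t1 %o% c(1, 2, 0) + t2 %o% c(0, 1, -1))
  pr <- soil_pca_with_outliers(r2, k = 2)
  expect_gt(sum(pr$pca$explained_variance_pct), 100 - 1e-6)
})

test_that("Kruskal-Wallis H matches oracles and handles total ties", {
  allsame <- kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3))
  expect_equal(allsame$H, 0)
  expect_equal(allsame$p, 1)
  vals <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  grp <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(vals, grp)
  expect_equal(kw$H, 7.2, tolerance = 1e-9)
  expect_equal(kw$H, kw_oracle(vals, grp), tolerance = 1e-12)
  # ties + comparison against the reference implementation in stats
  set.seed(64)
  v2 <- sample(rep(1:6, 4))
  g2 <- rep(c("a", "b", "c", "d"), 6)
  kw2 <- kruskal_wallis(v2, g2)
  ref <- stats::kruskal.test(v2, factor(g2))
  expect_equal(kw2$H, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(kw2$p, ref$p.value, tolerance = 1e-9)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("the chi-squared p value agrees with a permutation null", {
  set.seed(65)
  vals <- rnorm(18, mean = rep(c(0, 0.8, 1.6), each = 6))
  grp <- rep(c("a", "b", "c"), each = 6)
  kw <- kruskal_wallis(vals, grp)
  B <- 4000
  perm <- vapply(seq_len(B), function(i)
    kw_oracle(vals, sample(grp)), numeric(1))
  p_perm <- (1 + sum(perm >= kw$H - 1e-12)) / (B + 1)
  mc_se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(kw$p - p_perm), 4 * mc_se + 0.02)
})

test_that("rank LSD: identical groups ~, separated groups !=, symmetry", {
  set.seed(66)
  vals <- c(rnorm(9), rnorm(9))
  grp <- rep(c("a", "b"), each = 9)
  same <- lsd_rank_posthoc(c(vals[1:9], vals[1:9]), grp)
  expect_false(same["a", "b"])
  sep <- lsd_rank_posthoc(c(1:9, 101:109), grp, alpha = 0.05)
  expect_true(sep["a", "b"])
  v3 <- rnorm(21)
  g3 <- rep(c("a", "b", "c"), 7)
  m3 <- lsd_rank_posthoc(v3, g3)
  expect_identical(m3, t(m3))
  expect_true(all(!diag(m3)))
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(67)
  vals <- rexp(24)
  grp <- rep(c("a", "b", "c", "d"), 6)
  h1 <- kruskal_wallis(vals, grp)$H
  expect_equal(kruskal_wallis(log(vals), grp)$H, h1)
  expect_equal(kruskal_wallis(vals^3, grp)$H, h1)
})

test_that("compact letter displays encode the significance pattern", {
  g3 <- c("A", "B", "C")
  none <- matrix(FALSE, 3, 3, dimnames = list(g3, g3))
  expect_equal(unname(compact_letter_display(none)), rep("a", 3))
  all_sig <- matrix(TRUE, 3, 3, dimnames = list(g3, g3))
  diag(all_sig) <- FALSE
  expect_equal(unname(compact_letter_display(all_sig)), c("a", "b", "c"))
  # chain A != C, A ~ B, B ~ C -> a, ab, b
  chain <- matrix(FALSE, 3, 3, dimnames = list(g3, g3))
  chain["A", "C"] <- chain["C", "A"] <- TRUE
  expect_equal(unname(compact_letter_display(chain)), c("a", "ab", "b"))
  # decode(encode) recovers arbitrary random patterns
  set.seed(68)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    m <- matrix(FALSE, k, k, dimnames = list(letters[1:k], letters[1:k]))
    up <- upper.tri(m)
    m[up] <- sample(c(TRUE, FALSE), sum(up), replace = TRUE)
    m <- m | t(m)
    cld <- compact_letter_display(m)
    expect_identical(decode_letter_display(cld), m)
  }
})

test_that("environment correlation: join contract, positive and negative controls", {
  # noiseless spectra -> a site covariate that is an exact linear
  # functional of each spectrum
  cfg <- synth_config(replicates_per_side = 1, noise_sd = 0,
                      scatter_sd = 0, baseline_coef_sd = 0,
                      leaf_position_effect_sd = 0, seed = 69)
  gd <- generate_dataset(cfg)
  pp <- preprocess_pipeline(gd$dataset)
  w <- exp(-(as.numeric(pp$grid) - 1500)^2 / 5000)
  site_val <- tapply(as.numeric(pp$absorbance %*% w), pp$meta$site, mean)
  cov_tab <- data.frame(site = names(site_val), marker = as.numeric(site_val))
  rep1 <- env_correlation_report(pp, cov_tab, by = "site", max_lv = 5,
                                 cv_folds = 7)
  expect_gt(rep1$cv_r2[rep1$covariate == "marker"], 0.99)
  expect_equal(rep1$verdict[rep1$covariate == "marker"], "correlated")
  # site-constant join: every spectrum of a site receives that site's value
  joined <- cov_tab$marker[match(pp$meta$site, cov_tab$site)]
  expect_equal(as.numeric(table(joined)), as.numeric(table(pp$meta$site)),
               ignore_attr = TRUE)
  # independent covariate -> minimal correlation. The null world must
  # carry no site signal in the spectra: with injected site effects a
  # site-constant covariate is decodable from the spectra by design.
  cfg0 <- synth_config(replicates_per_side = 1, effects = NULL, seed = 169)
  pp0 <- preprocess_pipeline(generate_dataset(cfg0)$dataset)
  set.seed(70)
  rnd <- data.frame(site = SITE_CODES, noisecov = rnorm(7))
  rep2 <- env_correlation_report(pp0, rnd, by = "site", max_lv = 5,
                                 cv_folds = 7)
  expect_equal(rep2$verdict[rep2$covariate == "noisecov"],
               "minimal correlation")
  # unmatched join keys error out loudly
  bad <- data.frame(site = c("SRC", "ZZZ"), v = c(1, 2))
  expect_error(env_correlation_report(pp, bad, by = "site"),
               "no covariate values")
})
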