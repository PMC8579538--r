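full_grid <- seq(4000, 400, by = -4)

test_that("fingerprint cut keeps exactly the closed-interval grid points", {
  ds <- spectral_dataset(matrix(rnorm(length(full_grid)), 1), full_grid)
  cut <- cut_region(ds, 900, 1800)
  expect_equal(ncol(cut$absorbance), 226)  # multiples of 4 in [900, 1800]
  expect_equal(range(as.numeric(cut$grid)), c(900, 1800))
  # full-range cut is the identity on the data
  same <- cut_region(ds, 400, 4000)
  expect_equal(same$absorbance, ds$absorbance, ignore_attr = TRUE)
  expect_error(cut_region(ds, 1800, 900), "lo must be")
  expect_error(cut_region(ds, 10, 20), "no grid points")
})

test_that("SG second derivative is exact on polynomials and zeros constants", {
  g <- toy_grid(40)
  ds <- spectral_dataset(rbind(g^2, rep(3, 40)), g)
  out <- savitzky_golay(ds, preprocess_config())
  expect_equal(out$absorbance[1, ], rep(2, 40), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(out$absorbance[2, ], rep(0, 40), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("SG filter matches the per-window polynomial-fit oracle", {
  set.seed(11)
  g <- toy_grid(60)
  y <- rnorm(60)
  ds <- spectral_dataset(matrix(y, 1), g)
  for (d in c(1, 2)) {
    cfg <- preprocess_config(sg_window = 9, sg_polyorder = 2, sg_deriv = d)
    ours <- savitzky_golay(ds, cfg)$absorbance[1, ]
    expect_lt(max(abs(ours - sg_oracle(y, g, 9, 2, d))), 1e-9)
  }
})

test_that("SG operator is linear and reduces to identity at deriv 0", {
  set.seed(12)
  g <- toy_grid(30)
  x <- rnorm(30); y <- rnorm(30)
  cfg <- preprocess_config(sg_window = 7, sg_polyorder = 2, sg_deriv = 2)
  sg <- function(v) savitzky_golay(spectral_dataset(matrix(v, 1), g),
                                   cfg)$absorbance[1, ]
  expect_equal(sg(2 * x + 3 * y), 2 * sg(x) + 3 * sg(y), tolerance = 1e-10)
  id_cfg <- preprocess_config(sg_window = 5, sg_polyorder = 4, sg_deriv = 0)
  out <- savitzky_golay(spectral_dataset(matrix(x, 1), g),
                        id_cfg)$absorbance[1, ]
  expect_equal(out[3:28], x[3:28], tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(savitzky_golay(spectral_dataset(matrix(x[1:3], 1),
                                               g[1:3]),
                              preprocess_config(sg_window = 9)),
               "window")
})

test_that("vector normalisation: 3-4-5, idempotence, scale invariance", {
  g <- toy_grid(2)
  ds <- spectral_dataset(matrix(c(3, 4), 1), g)
  out <- vector_normalize(ds)
  expect_equal(out$absorbance[1, ], c(0.6, 0.8), ignore_attr = TRUE)
  expect_equal(vector_normalize(out)$absorbance, out$absorbance)
  scaled <- spectral_dataset(7.3 * matrix(c(3, 4), 1), g)
  expect_equal(vector_normalize(scaled)$absorbance, out$absorbance)
  expect_error(vector_normalize(spectral_dataset(matrix(0, 1, 2), g)),
               "zero-norm spectrum at row\\(s\\) 1")
  set.seed(13)
  many <- vector_normalize(spectral_dataset(matrix(rnorm(200), 10), toy_grid(20)))
  expect_equal(rowSums(many$absorbance^2), rep(1, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("mean-centering uses the training mean for the test set", {
  g <- toy_grid(2)
  tr <- spectral_dataset(rbind(c(0, 2), c(2, 0)), g)
  te <- spectral_dataset(matrix(c(1, 1), 1), g)  # equals the train mean
  ctr <- mean_center(tr, te)
  expect_equal(ctr$train$absorbance, rbind(c(-1, 1), c(1, -1)),
               ignore_attr = TRUE)
  expect_equal(ctr$apply_to$absorbance, matrix(0, 1, 2), ignore_attr = TRUE)
  expect_equal(colMeans(ctr$train$absorbance), c(0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  two_same <- spectral_dataset(rbind(c(5, 7), c(5, 7)), g)
  expect_true(all(mean_center(two_same)$train$absorbance == 0))
  bad <- spectral_dataset(matrix(0.5, 1, 3), toy_grid(3))
  expect_error(mean_center(tr, bad), "grids differ")
})

test_that("rubber-band correction: lines vanish, peaks survive, tilt invariant", {
  g <- toy_grid(200)  # wide enough that the Gaussian tails reach ~zero
  line <- 0.01 * g + 3
  ds <- spectral_dataset(matrix(line, 1), g)
  expect_equal(rubberband_baseline(ds)$absorbance[1, ], rep(0, 200),
               tolerance = 1e-10, ignore_attr = TRUE)
  peak <- exp(-(g - 1400)^2 / (2 * 10^2))
  cor1 <- rubberband_baseline(spectral_dataset(matrix(peak, 1),
                                               g))$absorbance[1, ]
  expect_equal(max(cor1), 1, tolerance = 1e-6)
  expect_true(all(cor1 >= -1e-10))
  expect_equal(cor1[c(1, 200)], c(0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  tilted <- peak + 0.002 * g - 1
  cor2 <- rubberband_baseline(spectral_dataset(matrix(tilted, 1),
                                               g))$absorbance[1, ]
  expect_equal(cor2, cor1, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rubber-band envelope equals the brute-force hull", {
  set.seed(14)
  g <- toy_grid(40)
  y <- rnorm(40) + 0.001 * g
  cor <- rubberband_baseline(spectral_dataset(matrix(y, 1),
                                              g))$absorbance[1, ]
  ord <- order(g)
  env <- bf_lower_envelope(g[ord], y[ord])
  expect_equal(cor[ord], y[ord] - env, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("pipeline applies cut -> SG -> normalise and logs provenance", {
  set.seed(15)
  ds <- spectral_dataset(matrix(rnorm(5 * length(full_grid)), 5) + 2,
                         full_grid)
  out <- preprocess_pipeline(ds)
  expect_equal(range(as.numeric(out$grid)), c(900, 1800))
  expect_equal(rowSums(out$absorbance^2), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_length(out$provenance, 3)
  raw <- preprocess_pipeline(ds, preprocess_config(normalize = "none"))
  expect_false(isTRUE(all.equal(rowSums(raw$absorbance^2), rep(1, 5))))
  # applying the pipeline twice is not idempotent, and provenance shows it
  twice <- preprocess_pipeline(out)
  expect_length(twice$provenance, 6)
  expect_false(isTRUE(all.equal(twice$absorbance, out$absorbance)))
})
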