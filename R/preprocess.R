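# Pre-processing chain: fingerprint cut, Savitzky-Golay derivative,
# vector normalisation, mean-centering, rubber-band baseline ----------------

#' Pre-processing configuration
#'
#' Defaults follow the standard biochemical-fingerprint protocol:
#' cut to 1800-900 cm^-1, 9-point Savitzky-Golay second derivative
#' (polynomial order 2), vector normalisation; mean-centering is applied
#' at model-fitting time (on the training set only), not here.
#'
#' @param cut_lo,cut_hi fingerprint window bounds, cm^-1.
#' @param sg_window odd window length in points.
#' @param sg_polyorder polynomial order of the local fit.
#' @param sg_deriv derivative order (<= `sg_polyorder`).
#' @param normalize `"vector"` (unit Euclidean norm) or `"none"`.
#' @param center logical; recorded for pipeline configs, centering itself
#'   happens in [mean_center()] at fit time.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(cut_lo = 900, cut_hi = 1800, sg_window = 9,
                              sg_polyorder = 2, sg_deriv = 2,
                              normalize = c("vector", "none"),
                              center = TRUE) {
  normalize <- match.arg(normalize)
  stopifnot(cut_lo < cut_hi)
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder", call. = FALSE)
  }
  if (sg_deriv > sg_polyorder) {
    stop("sg_deriv must not exceed sg_polyorder", call. = FALSE)
  }
  structure(list(cut_lo = cut_lo, cut_hi = cut_hi, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, sg_deriv = sg_deriv,
                 normalize = normalize, center = center),
            class = "preprocess_config")
}

#' Cut a dataset to a wavenumber window
#'
#' Keeps exactly the grid points `w` with `lo <= w <= hi` (closed interval).
#'
#' @param ds a [spectral_dataset()].
#' @param lo,hi window bounds in cm^-1, `lo < hi`.
#' @return the windowed dataset, provenance appended.
#' @export
cut_region <- function(ds, lo = 900, hi = 1800) {
  if (lo >= hi) stop("cut_region: lo must be < hi", call. = FALSE)
  g <- as.numeric(ds$grid)
  keep <- g >= lo & g <= hi
  if (!any(keep)) stop("cut_region: no grid points in [", lo, ", ", hi, "]",
                       call. = FALSE)
  out <- spectral_dataset(ds$absorbance[, keep, drop = FALSE], g[keep],
                          ds$meta, ds$provenance)
  log_step(out, sprintf("cut to [%g, %g] cm^-1 (%d points)", lo, hi,
                        sum(keep)))
}

# Savitzky-Golay -------------------------------------------------------------

# Coefficient row evaluating the d-th derivative (w.r.t. index offset) of a
# degree-p least-squares polynomial fitted at offsets `offs`, at offset x0.
sg_eval_row <- function(offs, p, d, x0) {
  A <- outer(offs, 0:p, `^`)
  # pseudo-inverse row: coefs of fitted polynomial are (A'A)^-1 A' y
  Pinv <- solve(crossprod(A), t(A))
  k <- d:p
  w <- numeric(p + 1)
  w[k + 1] <- factorial(k) / factorial(k - d) * x0^(k - d)
  as.numeric(w %*% Pinv)
}

#' Savitzky-Golay derivative smoothing
#'
#' Sliding-window least-squares polynomial fit; each point is replaced by
#' the fitted derivative of order `sg_deriv` at that point. Boundary points
#' are handled by evaluating the polynomial fitted on the first/last full
#' window at the off-centre positions, so the grid length is preserved.
#' Derivatives are scaled to wavenumber units (divided by the signed grid
#' step raised to the derivative order), so values are per-(cm^-1)^deriv.
#'
#' @param ds a [spectral_dataset()].
#' @param cfg a [preprocess_config()] (only the `sg_*` fields are used).
#' @return dataset of SG-derivative spectra on the same grid.
#' @export
savitzky_golay <- function(ds, cfg = preprocess_config()) {
  m <- cfg$sg_window
  p <- cfg$sg_polyorder
  d <- cfg$sg_deriv
  n <- ncol(ds$absorbance)
  if (n < m) stop("savitzky_golay: window (", m, ") longer than spectrum (",
                  n, ")", call. = FALSE)
  h <- (m - 1L) %/% 2L
  g <- as.numeric(ds$grid)
  step <- mean(diff(g))  # signed; negative on the canonical descending grid
  offs <- seq(-h, h)
  centre_row <- sg_eval_row(offs, p, d, 0)
  # full filter matrix: n x n, sparse in structure but n<=~1000 here
  X <- ds$absorbance
  out <- matrix(0, nrow(X), n)
  # interior via filter
  for (j in seq.int(h + 1L, n - h)) {
    out[, j] <- X[, (j - h):(j + h), drop = FALSE] %*% centre_row
  }
  # edges: polynomial fitted on the boundary window, evaluated off-centre
  for (t in seq_len(h)) {
    row_l <- sg_eval_row(offs, p, d, t - 1L - h)   # position t, window 1..m
    out[, t] <- X[, 1:m, drop = FALSE] %*% row_l
    row_r <- sg_eval_row(offs, p, d, h - (t - 1L)) # position n-t+1
    out[, n - t + 1L] <- X[, (n - m + 1L):n, drop = FALSE] %*% row_r
  }
  out <- out / step^d
  res <- spectral_dataset(out, g, ds$meta, ds$provenance)
  log_step(res, sprintf("Savitzky-Golay derivative %d (window %d, order %d)",
                        d, m, p))
}

#' Vector normalisation
#'
#' Scales every spectrum to unit Euclidean norm, removing pathlength /
#' contact-pressure intensity effects.
#'
#' @param ds a [spectral_dataset()].
#' @return normalised dataset.
#' @export
vector_normalize <- function(ds) {
  nrm <- sqrt(rowSums(ds$absorbance^2))
  zero <- which(nrm == 0)
  if (length(zero)) {
    stop("vector_normalize: zero-norm spectrum at row(s) ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  out <- spectral_dataset(ds$absorbance / nrm, as.numeric(ds$grid), ds$meta,
                          ds$provenance)
  log_step(out, "vector normalised (unit Euclidean norm)")
}

#' Mean-center by the training mean
#'
#' Subtracts the column means of `train` from both `train` and (optionally)
#' `apply_to`. Centering an external test set by the *training* mean is
#' what keeps the test set external.
#'
#' @param train a [spectral_dataset()].
#' @param apply_to optional second dataset on the same grid.
#' @return list with `train`, `apply_to` (or `NULL`) and `mean`.
#' @export
mean_center <- function(train, apply_to = NULL) {
  if (nrow(train$absorbance) == 0) stop("mean_center: empty training set",
                                        call. = FALSE)
  mu <- colMeans(train$absorbance)
  ctr <- function(ds) {
    out <- spectral_dataset(sweep(ds$absorbance, 2, mu), as.numeric(ds$grid),
                            ds$meta, ds$provenance)
    log_step(out, "mean-centered by training mean")
  }
  out_apply <- NULL
  if (!is.null(apply_to)) {
    if (!isTRUE(all.equal(as.numeric(train$grid), as.numeric(apply_to$grid),
                          tolerance = 1e-9))) {
      stop("mean_center: train and apply_to grids differ", call. = FALSE)
    }
    out_apply <- ctr(apply_to)
  }
  list(train = ctr(train), apply_to = out_apply, mean = mu)
}

# Rubber-band baseline -------------------------------------------------------

# lower convex hull (Andrew monotone chain) of points sorted by x ascending;
# returns indices into the sorted order
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      # pop b if it lies above segment a-i
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Rubber-band baseline correction
#'
#' Subtracts the lower convex-hull envelope of each spectrum (the
#' "rubber band" stretched under the curve). The corrected spectrum is
#' non-negative and zero at both endpoints; used for raw-spectrum peak
#' height comparisons, not for the derivative classification pipeline.
#'
#' @param ds a [spectral_dataset()].
#' @return baseline-corrected dataset.
#' @export
rubberband_baseline <- function(ds) {
  g <- as.numeric(ds$grid)
  if (length(g) < 3) stop("rubberband_baseline: need >= 3 points",
                          call. = FALSE)
  ord <- order(g)  # ascending for the hull; orientation is immaterial
  ga <- g[ord]
  X <- ds$absorbance
  out <- X
  for (i in seq_len(nrow(X))) {
    ya <- X[i, ord]
    hi <- lower_hull_idx(ga, ya)
    base <- stats::approx(ga[hi], ya[hi], xout = ga, rule = 2)$y
    out[i, ord] <- ya - base
  }
  res <- spectral_dataset(out, g, ds$meta, ds$provenance)
  log_step(res, "rubber-band baseline corrected (lower convex hull)")
}

#' Full pre-processing pipeline
#'
#' Applies, in order: fingerprint cut, Savitzky-Golay derivative, vector
#' normalisation. Mean-centering is deliberately deferred to model fitting
#' so that external test sets are centered by the training mean.
#'
#' @param ds a [spectral_dataset()].
#' @param cfg a [preprocess_config()].
#' @return pre-processed dataset with per-step provenance.
#' @export
preprocess_pipeline <- function(ds, cfg = preprocess_config()) {
  out <- cut_region(ds, cfg$cut_lo, cfg$cut_hi)
  out <- savitzky_golay(out, cfg)
  if (cfg$normalize == "vector") out <- vector_normalize(out)
  out
}
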