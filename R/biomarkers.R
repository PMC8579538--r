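# Spectral biomarkers from difference-between-mean-support-vector spectra ---

#' Bundled wavenumber -> molecular assignment table
#'
#' Literature-based tentative molecular assignments for fingerprint-region
#' wavenumbers (cm^-1), shipped as a versioned CSV asset. Includes e.g.
#' the lipid C=O stretch at 1736, the pectin ring mode at 1015 and the
#' glyphosate NH2+ marker at 1481 cm^-1. Reference keys are opaque
#' citation handles into the bundled bibliography.
#'
#' @param path optional path to a CSV with columns `wavenumber`,
#'   `assignment`, `reference`; defaults to the bundled asset.
#' @return data.frame with those three columns, wavenumber descending.
#' @export
assignment_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "biomarker_assignments.csv",
                        package = "ftirprint", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("wavenumber", "assignment", "reference") %in% names(tab)))
  tab[order(-tab$wavenumber), , drop = FALSE]
}

#' Mean support-vector spectrum of a class
#'
#' Unweighted mean over the unique stored support vectors that belong to
#' `class_label` within the relevant binary subproblem: for
#' `contrast = "pairwise"` the one-vs-one pair (`other` names the opposing
#' class); for `contrast = "one_vs_others"` the model must be a dedicated
#' two-class fit of the class against the pooled rest.
#'
#' @param m an `svm_rbf_model`.
#' @param class_label the class whose support vectors are averaged.
#' @param contrast `"pairwise"` or `"one_vs_others"`.
#' @param other the opposing class for the pairwise contrast (may be
#'   omitted for two-class models).
#' @return named list: `spectrum` (numeric vector) and `n_sv`.
#' @export
mean_sv_spectrum <- function(m, class_label,
                             contrast = c("pairwise", "one_vs_others"),
                             other = NULL) {
  contrast <- match.arg(contrast)
  if (contrast == "one_vs_others" || length(m$classes) == 2) {
    if (!class_label %in% m$classes) {
      stop("mean_sv_spectrum: class '", class_label, "' not in model",
           call. = FALSE)
    }
    pf <- m$pair_fits[[1]]
    rows <- pf$sv_rows[m$sv_class_labels[pf$sv_rows] == class_label]
  } else {
    if (is.null(other)) stop("mean_sv_spectrum: pairwise contrast in a ",
                             "multiclass model needs `other`", call. = FALSE)
    pi <- which(vapply(m$pair_fits, function(f)
      setequal(f$classes, c(class_label, other)), logical(1)))
    if (!length(pi)) stop("mean_sv_spectrum: no fitted pair ", class_label,
                          "/", other, call. = FALSE)
    pf <- m$pair_fits[[pi]]
    rows <- pf$sv_rows[m$sv_class_labels[pf$sv_rows] == class_label]
  }
  if (!length(rows)) {
    stop("mean_sv_spectrum: class '", class_label,
         "' has zero support vectors in this contrast", call. = FALSE)
  }
  list(spectrum = colMeans(m$support_vectors[rows, , drop = FALSE]),
       n_sv = length(rows))
}

#' Difference between mean support-vector spectra
#'
#' `mean_sv(class_a) - mean_sv(class_b)`: positive excursions attribute
#' to `class_a`, negative to `class_b` (the "+/- coefficients"
#' convention of difference-spectrum plots). With `class_b = "others"`
#' the model must be a dedicated one-vs-rest fit whose second class is
#' labelled `"others"`.
#'
#' @param m an `svm_rbf_model` trained on pre-processed spectra.
#' @param class_a,class_b class labels (`class_b` may be `"others"`).
#' @param grid the wavenumber grid of the training space (numeric vector
#'   or `wavenumber_grid`).
#' @return a `difference_spectrum`: `grid`, `values`, `positive_class`,
#'   `negative_class`, `n_sv_pos`, `n_sv_neg`.
#' @export
difference_sv_spectrum <- function(m, class_a, class_b, grid) {
  contrast <- if (identical(class_b, "others")) "one_vs_others" else
    "pairwise"
  a <- mean_sv_spectrum(m, class_a, contrast, other = class_b)
  b <- mean_sv_spectrum(m, class_b, contrast, other = class_a)
  structure(
    list(grid = as.numeric(grid), values = a$spectrum - b$spectrum,
         positive_class = class_a, negative_class = class_b,
         n_sv_pos = a$n_sv, n_sv_neg = b$n_sv),
    class = "difference_spectrum"
  )
}

#' @export
print.difference_spectrum <- function(x, ...) {
  cat(sprintf("<difference_spectrum> %s (+) vs %s (-), %d points\n",
              x$positive_class, x$negative_class, length(x$values)))
  invisible(x)
}

#' Pick peaks from a difference spectrum
#'
#' Local extrema of `|values|` with height at least
#' `min_prominence_frac * max(|values|)`, sorted by absolute height
#' (descending) and truncated to `max_peaks`. The signed height carries
#' the +/- class attribution.
#'
#' @param d a `difference_spectrum`.
#' @param max_peaks maximum number of peaks returned.
#' @param min_prominence_frac height threshold as a fraction of the global
#'   absolute maximum, in (0, 1].
#' @return data.frame with columns `wavenumber`, `signed_height`,
#'   `assignment` (empty), `assignment_distance` (NA), `reference` (empty);
#'   empty for a flat spectrum.
#' @export
pick_peaks <- function(d, max_peaks = 12, min_prominence_frac = 0.2) {
  stopifnot(max_peaks >= 1,
            min_prominence_frac > 0, min_prominence_frac <= 1)
  v <- abs(d$values)
  n <- length(v)
  vmax <- max(v)
  empty <- data.frame(wavenumber = numeric(0), signed_height = numeric(0),
                      assignment = character(0),
                      assignment_distance = numeric(0),
                      reference = character(0), stringsAsFactors = FALSE)
  if (vmax == 0) return(empty)
  # local maxima of |values|; a flat-topped plateau counts once, at its
  # left edge (strict rise from the left, non-strict fall to the right);
  # endpoints excluded
  is_peak <- logical(n)
  for (i in 2:(n - 1)) {
    is_peak[i] <- v[i] > v[i - 1] && v[i] >= v[i + 1]
  }
  idx <- which(is_peak & v >= min_prominence_frac * vmax)
  if (!length(idx)) return(empty)
  idx <- idx[order(v[idx], decreasing = TRUE)]
  idx <- idx[seq_len(min(max_peaks, length(idx)))]
  data.frame(wavenumber = d$grid[idx], signed_height = d$values[idx],
             assignment = "", assignment_distance = NA_real_,
             reference = "", stringsAsFactors = FALSE)
}

#' Assign picked peaks to molecular annotations
#'
#' Each peak is matched to the nearest table wavenumber within `tol`
#' cm^-1 (default two grid steps, the acquisition resolution). Ties go to
#' the smaller table wavenumber; peaks without a match within tolerance
#' keep an empty assignment.
#'
#' @param peaks data.frame from [pick_peaks()].
#' @param table assignment table (see [assignment_table()]).
#' @param tol matching tolerance in cm^-1.
#' @return the peaks data.frame with `assignment`, `assignment_distance`
#'   and `reference` filled in.
#' @export
assign_peaks <- function(peaks, table = assignment_table(), tol = 8) {
  stopifnot(tol > 0)
  if (!nrow(table)) stop("assign_peaks: empty assignment table",
                         call. = FALSE)
  for (i in seq_len(nrow(peaks))) {
    dist <- abs(table$wavenumber - peaks$wavenumber[i])
    j <- which(dist == min(dist))
    if (length(j) > 1) j <- j[which.min(table$wavenumber[j])]
    if (dist[j] <= tol) {
      peaks$assignment[i] <- table$assignment[j]
      peaks$assignment_distance[i] <- dist[j]
      peaks$reference[i] <- table$reference[j]
    } else {
      peaks$assignment[i] <- ""
      peaks$assignment_distance[i] <- NA_real_
      peaks$reference[i] <- ""
    }
  }
  peaks
}

#' One-vs-rest SVM fit for pooled "others" contrasts
#'
#' Site-level difference spectra contrast one site against the pooled
#' remaining sites; reusing one-vs-one pairs cannot produce that pooled
#' contrast, so a dedicated two-class fit is used, with the rest relabelled
#' `"others"`.
#'
#' @param X training matrix; `labels` the full multi-class labels.
#' @param class_label the positive class.
#' @param ... forwarded to [fit_svm_rbf()].
#' @return an `svm_rbf_model` with classes `c(class_label, "others")`.
#' @export
fit_one_vs_others_svm <- function(X, labels, class_label, ...) {
  labels <- as.character(labels)
  if (!class_label %in% labels) {
    stop("fit_one_vs_others_svm: class '", class_label, "' absent",
         call. = FALSE)
  }
  y <- ifelse(labels == class_label, class_label, "others")
  fit_svm_rbf(X, y, ...)
}
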