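# Cross-validation folds, external split and quality parameters -------------

#' Venetian-blinds fold assignment
#'
#' Sample `i` (in dataset order) goes to fold `((i - 1) mod k) + 1`,
#' interleaving consecutive samples across folds like the slats of a
#' venetian blind. Deterministic.
#'
#' @param n number of samples.
#' @param k number of folds (`2 <= k <= n`).
#' @return integer vector of fold indices in `1..k`.
#' @export
venetian_blinds <- function(n, k = 10) {
  if (k < 2) stop("venetian_blinds: k must be >= 2", call. = FALSE)
  if (n < k) stop("venetian_blinds: n (", n, ") < k (", k, ")",
                  call. = FALSE)
  ((seq_len(n) - 1L) %% k) + 1L
}

#' Stratified random training/test split
#'
#' Randomly divides spectra into a training set (fraction `frac`) and an
#' external test set. Stratification (default: by the classification
#' label) keeps every class represented; per-stratum counts are rounded
#' so that the total training size equals `round(frac * n)`. The split
#' unit is the spectrum; `group_by` (e.g. a leaf identifier) switches to
#' grouped splitting to avoid pseudo-replicate leakage.
#'
#' @param ds a [spectral_dataset()] (or anything with `$meta` rows).
#' @param frac training fraction in (0, 1).
#' @param seed integer seed; the split is reproducible given the seed.
#' @param stratify_by metadata column to stratify on, or `NULL`.
#' @param group_by optional metadata column whose levels must not be split
#'   across train and test.
#' @return list with `train` and `test` datasets and the logical `in_train`.
#' @export
split_70_30 <- function(ds, frac = 0.7, seed = 1, stratify_by = "region",
                        group_by = NULL) {
  if (frac <= 0 || frac >= 1) stop("split_70_30: frac must be in (0,1)",
                                   call. = FALSE)
  n <- nrow(ds$absorbance)
  strata <- if (!is.null(stratify_by)) {
    as.character(ds$meta[[stratify_by]])
  } else {
    rep("all", n)
  }
  rng <- local_rng(seed)
  in_train <- rep(FALSE, n)
  if (is.null(group_by)) {
    sizes <- table(strata)
    if (any(sizes < 2)) {
      stop("split_70_30: stratum smaller than 2: ",
           paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
    }
    target_total <- round(frac * n)
    raw <- frac * as.numeric(sizes)
    take <- floor(raw)
    rem <- target_total - sum(take)
    if (rem > 0) {
      ord <- order(raw - take, decreasing = TRUE)
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
    } else if (rem < 0) {
      ord <- order(raw - take)
      take[ord[seq_len(-rem)]] <- take[ord[seq_len(-rem)]] - 1
    }
    for (si in seq_along(sizes)) {
      rows <- which(strata == names(sizes)[si])
      in_train[sample_rng(rng, rows, take[si])] <- TRUE
    }
  } else {
    grp <- as.character(ds$meta[[group_by]])
    for (s in unique(strata)) {
      gl <- unique(grp[strata == s])
      ntr <- round(frac * length(gl))
      tr_g <- sample_rng(rng, gl, ntr)
      in_train[strata == s & grp %in% tr_g] <- TRUE
    }
  }
  list(train = subset_spectra(ds, which(in_train)),
       test = subset_spectra(ds, which(!in_train)),
       in_train = in_train)
}

# Seeded RNG scoped to a closure, leaving the global stream untouched.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  env
}

sample_rng <- function(rng, x, size) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", rng$state, globalenv())
  out <- sample(x, size)
  rng$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  out
}

#' Per-class quality parameters
#'
#' One-vs-all confusion summaries per class: sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, and the per-class
#' "accuracy" defined as `(sensitivity + specificity)/2` -- the convention
#' used by the chemometric toolboxes this package mirrors, distinct from
#' overall accuracy (`correct/n`). Precision of a never-predicted class is
#' `NaN`. All values are percentages and are not rounded; use
#' [format_metrics()] for display rounding (half-up to integers).
#'
#' @param true_labels,predicted_labels equal-length label vectors;
#'   predictions must fall within the known class set.
#' @return a `class_metrics` object: `per_class` data.frame,
#'   `overall_accuracy` (%), and `confusion` (true x predicted counts).
#' @export
quality_parameters <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (!length(true_labels)) stop("quality_parameters: empty input",
                                 call. = FALSE)
  if (length(true_labels) != length(predicted_labels)) {
    stop("quality_parameters: length mismatch", call. = FALSE)
  }
  classes <- sort(unique(true_labels))
  if (!all(predicted_labels %in% classes)) {
    bad <- setdiff(unique(predicted_labels), classes)
    stop("quality_parameters: predicted label(s) outside known class set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(true_labels)
  conf <- table(factor(true_labels, classes), factor(predicted_labels,
                                                     classes))
  per <- data.frame(class = classes, accuracy = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    precision = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    tp <- conf[i, i]
    fn <- sum(conf[i, ]) - tp
    fp <- sum(conf[, i]) - tp
    tn <- n - tp - fn - fp
    sens <- 100 * tp / (tp + fn)
    spec <- 100 * tn / (tn + fp)
    prec <- if (tp + fp == 0) NaN else 100 * tp / (tp + fp)
    per$sensitivity[i] <- sens
    per$specificity[i] <- spec
    per$precision[i] <- prec
    per$accuracy[i] <- (sens + spec) / 2
  }
  structure(list(per_class = per,
                 overall_accuracy = 100 * sum(diag(conf)) / n,
                 confusion = conf, n = n),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("<class_metrics> n=%d, overall accuracy %.1f%%\n", x$n,
              x$overall_accuracy))
  print(format_metrics(x), row.names = FALSE)
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Display-rounded metrics table
#'
#' @param x a `class_metrics` object.
#' @return data.frame with integer percentages (half-up rounding, as
#'   printed in classification quality tables).
#' @export
format_metrics <- function(x) {
  per <- x$per_class
  for (cn in c("accuracy", "sensitivity", "specificity", "precision")) {
    per[[cn]] <- round_half_up(per[[cn]])
  }
  per
}

#' Write a metrics CSV (one row per class per algorithm)
#'
#' @param metrics named list of `class_metrics` objects (names = algorithm).
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(metrics, path) {
  rows <- do.call(rbind, lapply(names(metrics), function(alg) {
    per <- metrics[[alg]]$per_class
    cbind(data.frame(algorithm = alg, stringsAsFactors = FALSE), per)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
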