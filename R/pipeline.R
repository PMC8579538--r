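# Config-driven analysis drivers --------------------------------------------

#' Run configuration for the classification pipeline
#'
#' @param label_field classify by `"region"` or `"site"`.
#' @param preprocess a [preprocess_config()].
#' @param n_pcs PCA components for PCA-LDA.
#' @param cost,gamma fixed SVM hyperparameters; ignored when both grids
#'   are given.
#' @param cost_grid,gamma_grid optional tuning grids (venetian-blinds CV).
#' @param split_frac,split_seed external train/test split parameters.
#' @param cv_folds venetian-blinds folds for cross-validation.
#' @param do_cv compute cross-validated training metrics? (Costs one SVM
#'   and one PCA-LDA refit per fold.)
#' @param biomarker_max_peaks,biomarker_min_prominence,biomarker_tol
#'   peak picking and assignment settings.
#' @param out_dir output directory for report artifacts, or `NULL` to
#'   skip writing.
#' @return a `run_config` list.
#' @export
run_config <- function(label_field = c("region", "site"),
                       preprocess = preprocess_config(), n_pcs = 10,
                       cost = 10, gamma = 3.16, cost_grid = NULL,
                       gamma_grid = NULL, split_frac = 0.7, split_seed = 1,
                       cv_folds = 10, do_cv = TRUE,
                       biomarker_max_peaks = 12,
                       biomarker_min_prominence = 0.2, biomarker_tol = 8,
                       out_dir = NULL) {
  label_field <- match.arg(label_field)
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[order(names(cfg))]), f)
  unname(tools::md5sum(f))
}

#' Run the classification analysis
#'
#' Reproduces the standard chemometric discrimination workflow:
#' pre-process, stratified 70/30 external split, mean-center by the
#' training mean, fit PCA-LDA and RBF-SVM, evaluate by venetian-blinds
#' cross-validation and on the external test set, and extract
#' difference-between-mean-support-vector biomarkers (pairwise contrasts
#' at region level, one-vs-others contrasts at site level).
#'
#' @param ds a raw [spectral_dataset()] with parsed metadata.
#' @param cfg a [run_config()].
#' @return a report bundle (list): `metrics` (named list of
#'   `class_metrics` for train/cv/test per algorithm), `svm`, `pca_lda`
#'   models, `probabilities` (test-set SVM class probabilities),
#'   `biomarkers` (assigned peak tables per contrast),
#'   `difference_spectra`, `split`, `config`, `config_hash`, `log`.
#'   Artifacts are written as CSVs under `cfg$out_dir` when set.
#' @export
run_classification <- function(ds, cfg = run_config()) {
  t0 <- Sys.time()
  labels_all <- dataset_labels(ds, cfg$label_field)
  pp <- preprocess_pipeline(ds, cfg$preprocess)
  sp <- split_70_30(pp, frac = cfg$split_frac, seed = cfg$split_seed,
                    stratify_by = cfg$label_field)
  ctr <- mean_center(sp$train, sp$test)
  Xtr <- ctr$train$absorbance
  Xte <- ctr$apply_to$absorbance
  ytr <- dataset_labels(sp$train, cfg$label_field)
  yte <- dataset_labels(sp$test, cfg$label_field)
  log <- c(sprintf("label_field=%s n=%d train=%d test=%d", cfg$label_field,
                   length(labels_all), length(ytr), length(yte)),
           "test set centered by the training mean (no test-row statistics)")

  # hyperparameters
  cost <- cfg$cost; gamma <- cfg$gamma
  if (!is.null(cfg$cost_grid) && !is.null(cfg$gamma_grid)) {
    tn <- tune_svm(Xtr, ytr, cfg$cost_grid, cfg$gamma_grid,
                   cv = venetian_blinds(nrow(Xtr), cfg$cv_folds))
    cost <- tn$cost; gamma <- tn$gamma
    log <- c(log, sprintf("tuned SVM: cost=%g gamma=%g (cv acc %.3f)",
                          cost, gamma, tn$cv_accuracy))
  }

  # models
  lda <- fit_pca_lda(Xtr, ytr, n_pcs = cfg$n_pcs)
  svm <- fit_svm_rbf(Xtr, ytr, cost = cost, gamma = gamma)
  metrics <- list()
  metrics$pca_lda_train <- quality_parameters(ytr,
                                              predict_pca_lda(lda, Xtr)$labels)
  metrics$svm_train <- quality_parameters(ytr, predict_svm(svm, Xtr)$labels)
  te_lda <- predict_pca_lda(lda, Xte)
  te_svm <- predict_svm(svm, Xte)
  metrics$pca_lda_test <- quality_parameters(yte, te_lda$labels)
  metrics$svm_test <- quality_parameters(yte, te_svm$labels)

  if (isTRUE(cfg$do_cv)) {
    fold <- venetian_blinds(nrow(Xtr), cfg$cv_folds)
    pred_lda <- pred_svm <- character(nrow(Xtr))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      lf <- fit_pca_lda(Xtr[tr, , drop = FALSE], ytr[tr],
                        n_pcs = cfg$n_pcs)
      pred_lda[!tr] <- predict_pca_lda(lf, Xtr[!tr, , drop = FALSE])$labels
      sf <- fit_svm_rbf(Xtr[tr, , drop = FALSE], ytr[tr], cost = cost,
                        gamma = gamma, probability = FALSE)
      pred_svm[!tr] <- predict_svm(sf, Xtr[!tr, , drop = FALSE])$labels
    }
    metrics$pca_lda_cv <- quality_parameters(ytr, pred_lda)
    metrics$svm_cv <- quality_parameters(ytr, pred_svm)
  }

  # biomarkers
  grid <- as.numeric(pp$grid)
  classes <- sort(unique(ytr))
  diffs <- list()
  if (cfg$label_field == "region") {
    for (pr in utils::combn(classes, 2, simplify = FALSE)) {
      d <- difference_sv_spectrum(svm, pr[1], pr[2], grid)
      diffs[[paste(pr[1], "vs", pr[2])]] <- d
    }
  } else {
    for (cl in classes) {
      mo <- fit_one_vs_others_svm(Xtr, ytr, cl, cost = cost, gamma = gamma,
                                  probability = FALSE)
      diffs[[paste(cl, "vs others")]] <-
        difference_sv_spectrum(mo, cl, "others", grid)
    }
  }
  tab <- assignment_table()
  biomarkers <- lapply(diffs, function(d) {
    assign_peaks(pick_peaks(d, cfg$biomarker_max_peaks,
                            cfg$biomarker_min_prominence),
                 tab, tol = cfg$biomarker_tol)
  })

  bundle <- list(
    metrics = metrics, svm = svm, pca_lda = lda,
    probabilities = data.frame(label = sp$test$meta$label,
                               true = yte, predicted = te_svm$labels,
                               te_svm$probabilities,
                               check.names = FALSE),
    biomarkers = biomarkers, difference_spectra = diffs, split = sp,
    config = cfg, config_hash = config_hash(cfg),
    log = c(log, sprintf("svm N_SV=%d", svm$n_sv),
            sprintf("elapsed %.1fs", as.numeric(Sys.time() - t0,
                                                units = "secs")))
  )
  if (!is.null(cfg$out_dir)) write_classification_bundle(bundle, cfg$out_dir)
  bundle
}

write_classification_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# config_hash=%s seed=%d", bundle$config_hash,
                 bundle$config$split_seed)
  mpath <- file.path(out_dir, "metrics.csv")
  rows <- write_metrics_csv(bundle$metrics, mpath)
  # prepend hash comment deterministically
  txt <- readLines(mpath)
  writeLines(c(hdr, txt), mpath)
  utils::write.csv(bundle$probabilities,
                   file.path(out_dir, "probabilities.csv"),
                   row.names = FALSE)
  bm <- do.call(rbind, lapply(names(bundle$biomarkers), function(nm) {
    b <- bundle$biomarkers[[nm]]
    if (!nrow(b)) return(NULL)
    cbind(data.frame(comparison = nm, stringsAsFactors = FALSE), b)
  }))
  utils::write.csv(bm, file.path(out_dir, "biomarkers.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$difference_spectra)) {
    d <- bundle$difference_spectra[[nm]]
    utils::write.csv(
      data.frame(wavenumber = d$grid, value = d$values),
      file.path(out_dir, paste0("diff_",
                                gsub("[^A-Za-z0-9]+", "_", nm), ".csv")),
      row.names = FALSE)
  }
  writeLines(c(hdr, bundle$log), file.path(out_dir, "run_log.txt"))
  invisible(rows)
}

#' Run the spectra-vs-environment correlation analysis
#'
#' Per-covariate PLS summaries of pre-processed spectra against soil
#' (per-site) and climate (per-region) covariates, soil PCA with
#' Hotelling-T2 outlier flags, and Kruskal-Wallis + rank-LSD letter
#' displays per soil variable.
#'
#' @param ds a raw [spectral_dataset()] with metadata.
#' @param soil soil table (site, replicate, five soil variables).
#' @param climate climate table (region plus climate variables), or
#'   `NULL` to skip.
#' @param preprocess a [preprocess_config()].
#' @param r2_threshold verdict threshold for "minimal correlation".
#' @param out_dir optional artifact directory.
#' @return bundle: `pls_report`, `soil_pca`, `soil_letters`
#'   (per-variable Kruskal-Wallis results and letter displays), `log`.
#' @export
run_env_correlation <- function(ds, soil, climate = default_climate_table(),
                                preprocess = preprocess_config(),
                                r2_threshold = 0.5, out_dir = NULL) {
  pp <- preprocess_pipeline(ds, preprocess)
  rep_soil <- env_correlation_report(pp, soil, by = "site",
                                     r2_threshold = r2_threshold)
  rep_soil$covariate_set <- "soil"
  rep_all <- rep_soil
  if (!is.null(climate)) {
    rep_cl <- env_correlation_report(pp, climate, by = "region",
                                     r2_threshold = r2_threshold)
    rep_cl$covariate_set <- "climate"
    rep_all <- rbind(rep_soil, rep_cl)
  }
  spca <- soil_pca_with_outliers(soil[, c("site", "replicate", SOIL_VARS)])
  letters_out <- lapply(stats::setNames(SOIL_VARS, SOIL_VARS), function(v) {
    kw <- kruskal_wallis(soil[[v]], soil$site)
    sig <- lsd_rank_posthoc(soil[[v]], soil$site)
    list(kw = kw, letters = compact_letter_display(sig))
  })
  bundle <- list(pls_report = rep_all, soil_pca = spca,
                 soil_letters = letters_out,
                 log = sprintf("env correlation: %d covariates, %d spectra",
                               nrow(rep_all), nrow(pp$absorbance)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rep_all, file.path(out_dir, "pls_report.csv"),
                     row.names = FALSE)
    let <- do.call(rbind, lapply(names(letters_out), function(v) {
      l <- letters_out[[v]]$letters
      data.frame(variable = v, site = names(l), letters = unname(l),
                 H = letters_out[[v]]$kw$H, p = letters_out[[v]]$kw$p,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(let, file.path(out_dir, "soil_letters.csv"),
                     row.names = FALSE)
  }
  bundle
}

# Flat key-value model archive -----------------------------------------------

#' Serialize a fitted model to a flat text archive
#'
#' Writes numeric/character components (vectors and matrices, one key per
#' component) to a plain-text `key<TAB>type<TAB>dims<TAB>values` file.
#' Intended for pipeline caching of PCA/PLS models; nested lists are
#' flattened with `$`-joined keys.
#'
#' @param obj a list-like model object.
#' @param path output file.
#' @export
write_flat_archive <- function(obj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#ftirprint-archive\tclass=", class(obj)[1]), con)
  emit <- function(x, key) {
    if (is.list(x) && !is.data.frame(x)) {
      for (nm in names(x)) emit(x[[nm]], paste(key, nm, sep = "$"))
    } else if (is.matrix(x)) {
      writeLines(paste(key, "matrix", paste(dim(x), collapse = "x"),
                       paste(format(as.numeric(x), digits = 17,
                                    trim = TRUE), collapse = ","),
                       sep = "\t"), con)
    } else if (is.numeric(x)) {
      writeLines(paste(key, "numeric", length(x),
                       paste(format(as.numeric(x), digits = 17,
                                    trim = TRUE), collapse = ","),
                       sep = "\t"), con)
    } else if (is.character(x)) {
      writeLines(paste(key, "character", length(x),
                       paste(x, collapse = ","), sep = "\t"), con)
    }
  }
  for (nm in names(obj)) emit(obj[[nm]], nm)
  invisible(path)
}

#' Read a flat model archive
#'
#' @param path archive written by [write_flat_archive()].
#' @return nested list with the archived components (numeric vectors,
#'   matrices and character vectors), `class` attribute restored.
#' @export
read_flat_archive <- function(path) {
  lines <- readLines(path)
  cls <- sub(".*class=", "", lines[1])
  out <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    key <- strsplit(parts[1], "$", fixed = TRUE)[[1]]
    val <- switch(parts[2],
      matrix = {
        d <- as.integer(strsplit(parts[3], "x")[[1]])
        matrix(as.numeric(strsplit(parts[4], ",")[[1]]), d[1], d[2])
      },
      numeric = as.numeric(strsplit(parts[4], ",")[[1]]),
      character = strsplit(parts[4], ",")[[1]]
    )
    out[[key]] <- val
  }
  class(out) <- cls
  out
}
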