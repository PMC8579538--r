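# Soil-trait statistics and spectra-vs-environment correlation ---------------

SOIL_VARS <- c("pH", "pct_LOI", "pct_water", "olsen_P", "C_to_N")
CLIMATE_VARS <- c("tmax", "tmin", "tmean", "sunshine_h", "rain_days",
                  "rain_ge1mm_days", "airfrost_days")

#' Autoscale a soil-trait table
#'
#' Centers each numeric column to mean 0 and scales to unit standard
#' deviation (n-1 denominator), making incommensurate units comparable
#' before PCA.
#'
#' @param table data.frame; non-numeric columns (e.g. `site`, `replicate`)
#'   are carried through as attributes, numeric columns are scaled.
#' @return list with `X` (scaled matrix), `center`, `scale`, `keys`
#'   (the non-numeric columns).
#' @export
autoscale <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  keys <- table[, !num, drop = FALSE]
  X <- as.matrix(table[, num, drop = FALSE])
  if (nrow(X) < 2) stop("autoscale: need >= 2 rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("autoscale: constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  mus <- colMeans(X)
  list(X = scale(X, center = mus, scale = sds)[, , drop = FALSE],
       center = mus, scale = sds, keys = keys)
}

#' Soil PCA with Hotelling-T2 outlier flagging
#'
#' PCA on the autoscaled soil table; rows whose Hotelling T2 statistic on
#' the first `k` scores exceeds the F-based control limit at `t2_alpha`
#' are flagged as outliers. Outliers are reported, not silently removed:
#' the refit excluding them is returned alongside the full-model fit.
#'
#' @param table soil data.frame (see [autoscale()]).
#' @param k number of components (default 2).
#' @param t2_alpha significance level of the T2 limit.
#' @return list: `pca` (full fit), `t2`, `t2_limit`, `outliers` (logical),
#'   `pca_refit` (fit excluding flagged rows; `NULL` if none flagged),
#'   `keys`.
#' @export
soil_pca_with_outliers <- function(table, k = 2, t2_alpha = 0.05) {
  sc <- autoscale(table)
  n <- nrow(sc$X)
  if (n < k + 2) stop("soil_pca_with_outliers: need >= k + 2 rows",
                      call. = FALSE)
  pca <- fit_pca(sc$X, k)
  lam <- pca$sdev^2
  t2 <- rowSums(sweep(pca$scores^2, 2, lam, "/"))
  lim <- k * (n - 1) * (n + 1) / (n * (n - k)) *
    stats::qf(1 - t2_alpha, k, n - k)
  out <- t2 > lim
  refit <- NULL
  if (any(out)) {
    sc2 <- autoscale(table[!out, , drop = FALSE])
    refit <- fit_pca(sc2$X, k)
  }
  list(pca = pca, t2 = t2, t2_limit = lim, outliers = out,
       pca_refit = refit, keys = sc$keys)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction; p value from the
#' chi-squared approximation on g-1 degrees of freedom. When all values
#' are tied H is defined as 0 (p = 1).
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with `H`, `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  g <- unique(groups)
  if (length(g) < 2) stop("kruskal_wallis: need >= 2 groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (corr == 0) 0 else H / corr
  df <- length(g) - 1
  list(H = H, p = stats::pchisq(H, df, lower.tail = FALSE), df = df, n = N)
}

#' Rank-based Fisher LSD post hoc comparisons
#'
#' Pairwise comparisons of mean ranks following a Kruskal-Wallis test
#' (Conover convention): groups i and j differ when
#' `|Rbar_i - Rbar_j|` exceeds
#' `t_{1-alpha/2, N-g} * sqrt(S2 * (N-1-H)/(N-g) * (1/n_i + 1/n_j))`,
#' with `S2` the variance of all ranks.
#'
#' @param values,groups as in [kruskal_wallis()].
#' @param alpha significance level.
#' @return symmetric logical matrix (`TRUE` = significantly different),
#'   zero (FALSE) diagonal; group order = sorted unique labels.
#' @export
lsd_rank_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  kw <- kruskal_wallis(values, groups)
  gl <- sort(unique(groups))
  N <- length(values)
  gN <- length(gl)
  r <- rank(values)
  S2 <- sum(r^2 - mean(r)^2) / (N - 1)
  rbar <- tapply(r, groups, mean)[gl]
  ns <- tapply(r, groups, length)[gl]
  tcrit <- stats::qt(1 - alpha / 2, N - gN)
  fac <- S2 * (N - 1 - kw$H) / (N - gN)
  fac <- max(fac, 0)
  sig <- matrix(FALSE, gN, gN, dimnames = list(gl, gl))
  for (i in seq_len(gN - 1)) {
    for (j in seq.int(i + 1, gN)) {
      lsd <- tcrit * sqrt(fac * (1 / ns[i] + 1 / ns[j]))
      s <- abs(rbar[i] - rbar[j]) > lsd
      sig[i, j] <- s
      sig[j, i] <- s
    }
  }
  sig
}

#' Compact letter display
#'
#' Insert-and-absorb letter assignment for a pairwise significance
#' matrix: two groups share at least one letter exactly when they are
#' *not* significantly different.
#'
#' @param sig symmetric logical matrix (TRUE = different), dimnames =
#'   group labels.
#' @param group_order optional ordering of groups for letter allocation
#'   (default: matrix order).
#' @return named character vector of letter strings per group.
#' @export
compact_letter_display <- function(sig, group_order = rownames(sig)) {
  stopifnot(isTRUE(all.equal(sig, t(sig))))
  g <- group_order
  k <- length(g)
  # columns of `sets`: letters as logical membership vectors over groups
  sets <- list(rep(TRUE, k))
  names_idx <- stats::setNames(seq_len(k), g)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      if (!sig[g[i], g[j]]) next
      # the pair must not share a letter: split every set containing both
      s <- 1
      while (s <= length(sets)) {
        set <- sets[[s]]
        if (set[i] && set[j]) {
          a <- set; a[j] <- FALSE
          b <- set; b[i] <- FALSE
          sets[[s]] <- a
          sets[[length(sets) + 1]] <- b
        }
        s <- s + 1
      }
      # absorb: drop any set that is a (proper or equal, keeping the
      # first) subset of another
      str <- vapply(sets, function(x) paste(as.integer(x), collapse = ""),
                    "")
      keep <- !duplicated(str)
      for (s in seq_along(sets)) {
        if (!keep[s]) next
        for (t in seq_along(sets)) {
          if (s != t && keep[t] && !identical(sets[[s]], sets[[t]]) &&
              all(!sets[[s]] | sets[[t]])) {
            keep[s] <- FALSE  # s is strictly contained in t
            break
          }
        }
      }
      sets <- sets[keep]
    }
  }
  lets <- letters[seq_along(sets)]
  out <- vapply(seq_len(k), function(i) {
    paste(lets[vapply(sets, `[`, logical(1), i)], collapse = "")
  }, character(1))
  stats::setNames(out, g)
}

#' Decode a letter display back to its significance pattern
#'
#' @param cld named character vector from [compact_letter_display()].
#' @return symmetric logical matrix (TRUE = no shared letter =
#'   significantly different).
#' @export
decode_letter_display <- function(cld) {
  g <- names(cld)
  k <- length(g)
  sig <- matrix(FALSE, k, k, dimnames = list(g, g))
  split1 <- strsplit(cld, "")
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      shared <- length(intersect(split1[[i]], split1[[j]])) > 0
      sig[i, j] <- sig[j, i] <- !shared
    }
  }
  sig
}

#' PLS correlation of spectra against environmental covariates
#'
#' Joins per-site (or per-region) covariate values to every spectrum of
#' that site/region, then fits one PLS1 model per covariate with the
#' number of latent variables chosen by venetian-blinds cross-validation,
#' and reports cross-validated R2 and RMSE. A covariate is judged
#' "minimal correlation" when cv R2 falls below `r2_threshold`.
#'
#' @param spectra a pre-processed [spectral_dataset()] with metadata.
#' @param covariates data.frame with a join key column (`site` or
#'   `region`) plus numeric covariate columns. Replicated keys are
#'   averaged before the join.
#' @param by join key: `"site"` or `"region"`.
#' @param max_lv largest PLS model considered.
#' @param cv_folds venetian-blinds folds.
#' @param r2_threshold verdict threshold on cross-validated R2.
#' @return data.frame: covariate, n_lv, cv_r2, cv_rmse, verdict.
#' @export
env_correlation_report <- function(spectra, covariates,
                                   by = c("site", "region"), max_lv = 10,
                                   cv_folds = 10, r2_threshold = 0.5) {
  by <- match.arg(by)
  if (!by %in% names(covariates)) {
    stop("env_correlation_report: covariates lack a '", by, "' column",
         call. = FALSE)
  }
  keys_sp <- as.character(spectra$meta[[by]])
  num <- vapply(covariates, is.numeric, logical(1))
  num[names(covariates) %in% c(by, "replicate")] <- FALSE
  agg <- stats::aggregate(covariates[, num, drop = FALSE],
                          by = list(key = as.character(covariates[[by]])),
                          FUN = mean)
  missing <- setdiff(unique(keys_sp), agg$key)
  if (length(missing)) {
    stop("env_correlation_report: no covariate values for key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- spectra$absorbance
  n <- nrow(X)
  cv <- venetian_blinds(n, cv_folds)
  rows <- lapply(setdiff(names(agg), "key"), function(cn) {
    y <- agg[[cn]][match(keys_sp, agg$key)]
    if (stats::sd(y) == 0) {
      return(data.frame(covariate = cn, n_lv = NA_integer_,
                        cv_r2 = NA_real_, cv_rmse = NA_real_,
                        verdict = "degenerate (constant response)",
                        stringsAsFactors = FALSE))
    }
    nlv <- select_n_lv(X, y, max_lv, cv = cv)
    m <- fit_pls1(X, y, nlv, cv = cv)
    rmse <- m$cv_rmse_per_lv[nlv]
    r2 <- 1 - rmse^2 * n / sum((y - mean(y))^2)
    data.frame(covariate = cn, n_lv = nlv, cv_r2 = r2, cv_rmse = rmse,
               verdict = if (r2 < r2_threshold) "minimal correlation" else
                 "correlated", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
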