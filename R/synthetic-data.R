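# Hierarchical synthetic ATR-FTIR spectrum generator --------------------------
#
# Emulates the study design this package targets: 7 sites in 3 regions,
# 3 canes per site, 3 leaves per cane (New/Height/Mature), 2 leaf sides,
# 10 replicate spectra per side -> 1260 spectra from 63 leaves. Spectra are
# sums of Gaussian bands at literature fingerprint wavenumbers with
# class-specific amplitude/position effects, polynomial baseline drift,
# multiplicative scatter and additive noise. Ground truth is recorded so
# parameter-recovery tests can score the pipeline.

#' Default Gaussian peak library
#'
#' Fourteen bands centred on fingerprint wavenumbers that recur as
#' class-separating markers in leaf ATR-FTIR work (lipid ester carbonyls,
#' Amide I/II, tannin ring modes, glyphosate NH2+, carbohydrate/pectin
#' C-O), with widths 8-20 cm^-1 and amplitudes of order 0.1-1 AU.
#'
#' @return data.frame with columns `centre`, `width`, `amplitude`.
#' @export
default_peak_library <- function() {
  data.frame(
    centre    = c(1736, 1725, 1678, 1662, 1648, 1608, 1586, 1546, 1512,
                  1481, 1446, 1158, 1034, 1015),
    width     = c(10,   9,    12,   11,   14,   12,   13,   12,   10,
                  8,    11,   16,   14,   18),
    amplitude = c(0.35, 0.25, 0.20, 0.30, 0.80, 0.45, 0.50, 0.40, 0.25,
                  0.15, 0.30, 0.55, 0.60, 0.70)
  )
}

#' Default injected class effects
#'
#' The stated world of the generator: region-level effects echo the kind
#' of differences reported for UK knotweed regions (lower pectin band
#' amplitude and a small centre shift for NEE, lower tannin bands for
#' NEE, stronger amide bands in WS, lipid differences for NWE), plus one
#' small distinguishing amplitude tweak per site so site-level
#' classification has recoverable signal.
#'
#' @return data.frame with columns `level` ("region"/"site"), `target`,
#'   `wavenumber`, `amplitude_factor`, `centre_shift`.
#' @export
default_class_effects <- function() {
  rbind(
    data.frame(level = "region", target = "NEE",
               wavenumber = c(1015, 1034, 1608),
               amplitude_factor = c(0.75, 0.80, 0.80),
               centre_shift = c(4, 4, 0)),
    data.frame(level = "region", target = "WS",
               wavenumber = c(1648, 1586),
               amplitude_factor = c(1.20, 1.15), centre_shift = 0),
    data.frame(level = "region", target = "NWE",
               wavenumber = c(1736, 1446),
               amplitude_factor = c(1.15, 0.90), centre_shift = 0),
    data.frame(level = "site",
               target = c("SRC", "SLM", "SOM", "SAP", "ESA", "ESB", "EDB"),
               wavenumber = c(1678, 1512, 1158, 1725, 1512, 1736, 1446),
               amplitude_factor = c(1.10, 1.12, 1.10, 1.10, 0.90, 1.08,
                                    1.12),
               centre_shift = 0)
  )
}

#' Synthetic dataset configuration
#'
#' Defaults reproduce the full hierarchical design (1260 spectra, 63
#' leaves) on the 1800-900 cm^-1 fingerprint grid at 4 cm^-1 spacing.
#'
#' @param sites site codes (must be a subset of [SITE_CODES]).
#' @param canes_per_site,leaves_per_cane,sides_per_leaf,replicates_per_side
#'   design counts; leaves cycle through New/Height/Mature within a cane.
#' @param grid_lo,grid_hi,grid_step wavenumber grid (descending internally).
#' @param peak_library data.frame of Gaussian bands (centre, width,
#'   amplitude).
#' @param effects injected class effects ([default_class_effects()] or a
#'   like-shaped data.frame; may be `NULL` for a no-signal world).
#' @param baseline_order polynomial order of the random baseline drift.
#' @param baseline_coef_sd SD of the baseline polynomial coefficients (AU).
#' @param scatter_sd SD of log multiplicative scatter per spectrum.
#' @param noise_sd SD of additive Gaussian noise (AU).
#' @param leaf_position_effect_sd SD of the log amplitude factor drawn once
#'   per leaf position.
#' @param seed integer master seed; every spectrum uses a counter-based
#'   substream so subsetting the design leaves other spectra unchanged.
#' @return a `synth_config` list.
#' @export
synth_config <- function(sites = SITE_CODES, canes_per_site = 3,
                         leaves_per_cane = 3, sides_per_leaf = 2,
                         replicates_per_side = 10,
                         grid_lo = 900, grid_hi = 1800, grid_step = 4,
                         peak_library = default_peak_library(),
                         effects = default_class_effects(),
                         baseline_order = 2, baseline_coef_sd = 0.02,
                         scatter_sd = 0.05, noise_sd = 0.005,
                         leaf_position_effect_sd = 0.05, seed = 1) {
  stopifnot(all(sites %in% SITE_CODES),
            scatter_sd >= 0, noise_sd >= 0, leaf_position_effect_sd >= 0)
  structure(
    list(sites = sites, canes_per_site = canes_per_site,
         leaves_per_cane = leaves_per_cane, sides_per_leaf = sides_per_leaf,
         replicates_per_side = replicates_per_side,
         grid = seq(grid_hi, grid_lo, by = -grid_step),
         peak_library = peak_library, effects = effects,
         baseline_order = baseline_order,
         baseline_coef_sd = baseline_coef_sd,
         scatter_sd = scatter_sd, noise_sd = noise_sd,
         leaf_position_effect_sd = leaf_position_effect_sd,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate the full factorial sampling design
#'
#' @param cfg a [synth_config()].
#' @return data.frame of sample metadata in deterministic order (site,
#'   cane, leaf, side, replicate), with leaf positions cycling
#'   New/Height/Mature within each cane.
#' @export
generate_design <- function(cfg = synth_config()) {
  positions <- LEAF_POSITIONS[((seq_len(cfg$leaves_per_cane) - 1L) %% 3L)
                              + 1L]
  rows <- expand.grid(
    replicate = seq_len(cfg$replicates_per_side),
    leaf_side = c("upper", "lower")[seq_len(cfg$sides_per_leaf)],
    leaf = seq_len(cfg$leaves_per_cane),
    cane = seq_len(cfg$canes_per_site),
    site = cfg$sites,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("site", "cane", "leaf", "leaf_side", "replicate")]
  rows$leaf_position <- positions[rows$leaf]
  rows$region <- region_of(rows$site)
  rows$label <- sprintf("%s_c%d_%s_%s_r%02d", rows$site, rows$cane,
                        rows$leaf_position, rows$leaf_side, rows$replicate)
  rows[, c("label", "site", "region", "cane", "leaf", "leaf_position",
           "leaf_side", "replicate")]
}

# per-position amplitude factors drawn once from the master seed
leaf_position_factors <- function(cfg) {
  rng <- local_rng(cfg$seed)
  f <- exp(rnorm_rng(rng, 3, 0, cfg$leaf_position_effect_sd))
  stats::setNames(f, LEAF_POSITIONS)
}

rnorm_rng <- function(rng, n, mean = 0, sd = 1) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", rng$state, globalenv())
  out <- stats::rnorm(n, mean, sd)
  rng$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  out
}

# the deterministic (noiseless, unit-scatter, no-baseline) spectrum for one
# metadata row: Gaussian bands with all applicable class effects applied
noiseless_spectrum <- function(meta_row, cfg, leaf_factors) {
  g <- cfg$grid
  pl <- cfg$peak_library
  amp <- pl$amplitude
  cen <- pl$centre
  if (!is.null(cfg$effects) && nrow(cfg$effects)) {
    eff <- cfg$effects
    applicable <- (eff$level == "region" & eff$target == meta_row$region) |
      (eff$level == "site" & eff$target == meta_row$site)
    for (e in which(applicable)) {
      k <- which.min(abs(cen - eff$wavenumber[e]))
      amp[k] <- amp[k] * eff$amplitude_factor[e]
      cen[k] <- cen[k] + eff$centre_shift[e]
    }
  }
  amp <- amp * leaf_factors[[meta_row$leaf_position]]
  y <- numeric(length(g))
  for (k in seq_along(cen)) {
    y <- y + amp[k] * exp(-(g - cen[k])^2 / (2 * pl$width[k]^2))
  }
  y
}

spectrum_substream_seed <- function(master_seed, i) {
  # counter-based substream, kept inside 32-bit signed range
  (as.double(master_seed) * 48271 + i * 2654435761) %% 2147483647
}

#' Generate one spectrum plus its ground-truth record
#'
#' @param meta_row one row of [generate_design()] output.
#' @param cfg a [synth_config()].
#' @param index spectrum counter used to derive the per-spectrum random
#'   substream from the master seed.
#' @return list with `spectrum` and `truth` (a one-row data.frame:
#'   scatter factor, baseline coefficients, substream seed, leaf factor).
#' @export
generate_spectrum <- function(meta_row, cfg, index = 1L) {
  leaf_factors <- leaf_position_factors(cfg)
  clean <- noiseless_spectrum(meta_row, cfg, leaf_factors)
  sub_seed <- spectrum_substream_seed(cfg$seed, index)
  rng <- local_rng(sub_seed)
  nb <- cfg$baseline_order + 1L
  bcoef <- rnorm_rng(rng, nb, 0, cfg$baseline_coef_sd)
  u <- seq(-1, 1, length.out = length(cfg$grid))
  baseline <- as.numeric(outer(u, 0:(nb - 1L), `^`) %*% bcoef)
  scatter <- exp(rnorm_rng(rng, 1, 0, cfg$scatter_sd))
  noise <- rnorm_rng(rng, length(cfg$grid), 0, cfg$noise_sd)
  y <- scatter * (clean + baseline) + noise
  truth <- data.frame(
    label = meta_row$label, site = meta_row$site, region = meta_row$region,
    leaf_position = meta_row$leaf_position,
    leaf_factor = unname(leaf_factors[[meta_row$leaf_position]]),
    scatter = scatter, substream_seed = sub_seed,
    baseline_coefs = paste(format(bcoef, digits = 17), collapse = ";"),
    stringsAsFactors = FALSE
  )
  list(spectrum = y, truth = truth)
}

#' Generate a full synthetic dataset with ground truth
#'
#' @param cfg a [synth_config()].
#' @return list with `dataset` (a [spectral_dataset()]) and `truth`
#'   (per-spectrum record plus the injected `effects` table and
#'   `leaf_position_factors`).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  design <- generate_design(cfg)
  n <- nrow(design)
  A <- matrix(0, n, length(cfg$grid))
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    gs <- generate_spectrum(design[i, ], cfg, index = i)
    A[i, ] <- gs$spectrum
    truths[[i]] <- gs$truth
  }
  meta <- design[, c("label", "site", "region", "cane", "leaf",
                     "leaf_position", "leaf_side", "replicate")]
  ds <- spectral_dataset(A, cfg$grid, meta,
                         provenance = sprintf(
                           "synthetic dataset: %d spectra, seed %d",
                           n, cfg$seed))
  list(dataset = ds,
       truth = list(per_spectrum = do.call(rbind, truths),
                    effects = cfg$effects,
                    leaf_position_factors = leaf_position_factors(cfg)))
}

#' Default per-site soil means and SDs
#'
#' Synthetic stand-ins shaped like field soil panels: an acid high-C:N
#' site (EDB), organic-rich urban sites (SOM, SAP), a sandy low-organic
#' riverside site (ESB), and intermediate clay sites.
#'
#' @return list of two data.frames `means` and `sds`, rows = sites,
#'   columns = the five soil variables.
#' @export
default_soil_params <- function() {
  means <- data.frame(
    site = SITE_CODES,
    pH        = c(7.2, 6.3, 6.0, 6.8, 4.8, 5.0, 6.7),
    pct_LOI   = c(18, 20, 8, 9, 16, 12, 5),
    pct_water = c(35, 33, 22, 26, 12, 20, 10),
    olsen_P   = c(40, 80, 90, 85, 45, 18, 15),
    C_to_N    = c(12, 11, 13, 13, 24, 14, 9),
    stringsAsFactors = FALSE
  )
  sds <- data.frame(
    site = SITE_CODES,
    pH = 0.2, pct_LOI = 2, pct_water = 3, olsen_P = 8, C_to_N = 1.5,
    stringsAsFactors = FALSE
  )
  list(means = means, sds = sds)
}

#' Generate a synthetic soil table
#'
#' Three replicates per site drawn from per-site normal laws, truncated
#' to physical ranges (pH in (0,14), percentages in [0,100], positive
#' ratios). Optionally plants one extreme outlier row (high organic
#' matter and water, mimicking an anomalous urban sample) for testing
#' outlier flagging.
#'
#' @param params list of `means`/`sds` as from [default_soil_params()].
#' @param replicates replicates per site.
#' @param seed integer seed.
#' @param planted_outlier if `TRUE`, replicate 3 of site SAP is shifted by
#'   +8 site-SDs on `pct_LOI` and `pct_water`.
#' @return data.frame with columns site, replicate and the five soil
#'   variables.
#' @export
generate_soil <- function(params = default_soil_params(), replicates = 3,
                          seed = 1, planted_outlier = FALSE) {
  stopifnot(all(unlist(params$sds[, -1]) >= 0))
  rng <- local_rng(seed + 7919)
  rows <- list()
  for (si in seq_len(nrow(params$means))) {
    mu <- params$means[si, ]
    sd <- params$sds[params$sds$site == mu$site, ]
    for (r in seq_len(replicates)) {
      vals <- vapply(SOIL_VARS, function(v)
        rnorm_rng(rng, 1, mu[[v]], sd[[v]]), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        site = mu$site, replicate = r, t(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (planted_outlier) {
    i <- which(out$site == "SAP" & out$replicate == 3)
    sd <- params$sds[params$sds$site == "SAP", ]
    out$pct_LOI[i] <- out$pct_LOI[i] + 8 * sd$pct_LOI
    out$pct_water[i] <- out$pct_water[i] + 8 * sd$pct_water
  }
  out$pH <- pmin(pmax(out$pH, 0.1), 13.9)
  out$pct_LOI <- pmin(pmax(out$pct_LOI, 0), 100)
  out$pct_water <- pmin(pmax(out$pct_water, 0), 100)
  out$olsen_P <- pmax(out$olsen_P, 0.1)
  out$C_to_N <- pmax(out$C_to_N, 0.1)
  out
}

#' Default regional climate table
#'
#' One value per region per variable (growing-season summaries; the west
#' of Scotland is the wetter region). Used as a synthetic stand-in for
#' regional meteorological records.
#'
#' @return data.frame with a `region` column and the seven climate
#'   variables.
#' @export
default_climate_table <- function() {
  data.frame(
    region = c("NEE", "NWE", "WS"),
    tmax = c(17.9, 18.9, 17.2), tmin = c(9.8, 10.7, 9.6),
    tmean = c(13.9, 14.8, 13.4), sunshine_h = c(480, 505, 420),
    rain_days = c(35, 38, 47), rain_ge1mm_days = c(24, 27, 36),
    airfrost_days = c(0, 0, 1),
    stringsAsFactors = FALSE
  )
}
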