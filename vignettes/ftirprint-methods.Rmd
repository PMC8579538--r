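---
title: "Methods: chemometric discrimination of clonal plants from ATR-FTIR fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric discrimination of clonal plants from ATR-FTIR fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Attenuated total reflection Fourier-transform infrared (ATR-FTIR)
spectroscopy measures the vibrational absorbance of a leaf pressed against
an internal-reflection crystal, producing a spectrum over 4000–400 cm⁻¹ at
4 cm⁻¹ data spacing. Biomolecular bands concentrate in the *fingerprint
region*, 1800–900 cm⁻¹ (226 grid points). For clonal plants — genetically
uniform populations such as UK Japanese knotweed — the question is whether
leaves collected in different geographic regions carry reproducible
chemical differences despite genetic continuity. `ftirprint` implements
the standard chemometric answer to that question: derivative
pre-processing, PCA-LDA and RBF-SVM classification with venetian-blinds
cross-validation and an external test set, support-vector difference
spectra for biomarker discovery, and PLS regression of spectra against
soil and climate covariates.

The sampling hierarchy mirrored throughout the package is: 7 sites in 3
regions (four West-Scotland sites SOM/SAP/SLM/SRC, two North-West-England
sites ESA/ESB, one North-East-England site EDB), 3 canes per site, 3
leaves per cane (positions New/Height/Mature), 2 leaf sides, 10 replicate
spectra per side — 1260 spectra from 63 leaves.

## Pre-processing

`preprocess_pipeline()` applies, in order:

1. **Fingerprint cut** to the closed interval [900, 1800] cm⁻¹.
2. **Savitzky–Golay second derivative**, 9-point window. The polynomial
   order is fixed at 2 — the minimum supporting a second derivative and
   the common toolbox default; the source protocol states only the window
   length. Boundary points are handled by evaluating the polynomial
   fitted on the first/last full window at the off-centre positions, so
   the output grid equals the input grid (dropping 4 points per edge
   would silently change every downstream table dimension). Derivatives
   are scaled by the signed grid step to per-(cm⁻¹)² units; after vector
   normalisation this scaling is immaterial to classification, which is
   why the choice is not agonised over.
3. **Vector normalisation** to unit Euclidean norm (removes
   pathlength/contact-pressure effects).

**Mean-centering is deferred to fit time** (`mean_center()`): the
external test set is centered by the *training* mean, never its own, so
no test-row statistic leaks into the model.

`rubberband_baseline()` (lower convex-hull subtraction) is provided
separately for raw-spectrum peak-height comparisons — concentration
direction statements — and is not part of the derivative classification
chain.

One consequence of vector normalisation worth knowing when reading
difference spectra: amplifying a *dominant* band mostly rescales the
whole unit-norm spectrum, so part of the change re-appears with opposite
sign at the *other* bands. Injected-marker tests therefore use
non-dominant bands, and real markers at minor bands are the more
trustworthy ones.

## Classification

**PCA-LDA** (`fit_pca_lda()`): PCA scores (SVD-based; deterministic sign
convention, largest loading element positive) feed a linear discriminant
rule that assigns each spectrum to the class with the smallest Mahalanobis
distance under the pooled within-class covariance, with equal priors (the
design is balanced at site level and near-balanced at region level; priors
are configurable). Canonical directions for scores plots come from the
between/within generalized eigenproblem. The pooled covariance is
ridge-regularized (ε = 1e-8 relative) only when its condition number
exceeds 1e10. Distance ties break deterministically to the first class in
sorted label order.

**RBF-SVM** (`fit_svm_rbf()`): one-vs-one soft-margin SVMs with kernel
K(x, z) = exp(−γ‖x−z‖²), the γ convention under which the published
operating point C = 10, γ = 3.16 is stated. Each binary dual is solved by
sequential minimal optimisation (C++; maximal-violating-pair working-set
selection; stopping tolerance 1e-4 on the KKT violation, iteration cap
max(2·10⁵, 1000·n) with a diagnostic error on non-convergence). Training
rows are processed in stable input order, so refits are bit-reproducible.
`n_sv` counts *unique* support vectors across the pairs — the published
counts (439 for regions, 675 for sites) do not state their convention, so
the unambiguous one is used. Probabilities come from per-pair Platt
sigmoids fitted on 3-fold cross-validated decision values (avoiding
optimistic sigmoids) combined by pairwise coupling; the label itself comes
from voting, with ties broken by summed decision values.

`tune_svm()` searches a cost × γ grid exhaustively by venetian-blinds
cross-validation, ties toward smaller C then smaller γ.

## Validation

* `venetian_blinds(n, k)`: sample *i* (dataset order) goes to fold
  ((i−1) mod k)+1; deterministic, 10 splits by default. The original row
  order is used; an optional pre-shuffle is available through the split
  utilities.
* `split_70_30()`: stratified random split with per-stratum rounding so
  the training set is exactly round(0.7·n) — 882/378 at n = 1260. The
  split unit is the spectrum, mirroring the source protocol; because
  spectrum-level splitting leaks pseudo-replicates (20 spectra per leaf),
  a `group_by` mode that keeps whole leaves together is provided — use it
  when you want an honest generalisation estimate to unseen leaves.
* `quality_parameters()`: one-vs-all sensitivity, specificity, precision,
  and a per-class "accuracy" defined as **(sensitivity + specificity)/2**.
  This convention is deliberate and prominent: it is the only definition
  that reproduces every published per-class accuracy cell from its
  printed sensitivity/specificity pair (within ±1 rounding point), and it
  differs from overall accuracy (correct/n), which is reported separately.
  Display rounding is half-up to integer percent. Precision of a
  never-predicted class is NaN, not 0.

## Biomarkers

`difference_sv_spectrum()` contrasts the unweighted means of the support
vectors of two classes in the pre-processed space the SVM was trained in;
positive excursions attribute to the first class ("+ coefficients"
convention). Region-level analysis uses the one-vs-one pairs; site-level
analysis fits a dedicated one-vs-rest SVM per site (`fit_one_vs_others_svm()`)
because pooled "others" contrasts cannot be assembled from pairwise fits.
`pick_peaks()` takes local extrema of |values| above a height threshold
expressed as a fraction of the global maximum (default 0.2, configurable;
the labelling rule of the source figures is unstated, so the default is
calibrated to the synthetic-recovery property and exposed). Flat-topped
plateaus — common when a band centre falls midway between grid points —
count once. `assign_peaks()` matches peaks to a bundled literature
assignment table (CSV asset, includes the glyphosate NH₂⁺ marker at
1481 cm⁻¹) within ±8 cm⁻¹ (two grid steps, the acquisition resolution);
ties go to the smaller wavenumber.

## Soil and climate

Soil tables (pH, %LOI, %water, Olsen-P, C:N; three replicates per site)
are autoscaled before PCA; Hotelling-T² on the first two scores flags
outliers at the F-based 5% limit. Outliers are *flagged and reported*,
with the refit returned alongside — removal is an explicit caller choice,
mirroring how an anomalous field replicate would be handled manually.
Group comparisons use a tie-corrected Kruskal–Wallis test (χ² approximation,
defined as H = 0 when all values tie) followed by a rank-based Fisher-LSD
post hoc (Conover convention: mean ranks compared against
t·√(S²·(N−1−H)/(N−g)·(1/nᵢ+1/nⱼ))), α = 0.05, summarised as a compact
letter display built by insert-and-absorb (shared letter ⟺ not
significantly different; the encoding is exact and decodable).

`env_correlation_report()` regresses pre-processed spectra (predictors —
the standard chemometric orientation; the reverse is available through
`fit_pls1()` directly) on each covariate with PLS1 (NIPALS), latent
variables chosen by venetian-blinds CV, reporting cross-validated R² and
RMSE and a "minimal correlation" verdict below a configurable R²
threshold (default 0.5). Soil covariates join per site, climate per
region; region-resolution climate values make heavy within-covariate
ties, which is faithful to regional meteorological summaries.

## The synthetic world

`generate_dataset()` emulates the study design so the whole pipeline is
testable offline. Each spectrum is

> scatter · (Σ Gaussian bands + polynomial baseline) + noise,

with 14 default bands at literature marker wavenumbers (1736, 1725, 1678,
1662, 1648, 1608, 1586, 1546, 1512, 1481, 1446, 1158, 1034, 1015 cm⁻¹;
widths 8–20 cm⁻¹; amplitudes 0.15–0.8 AU). Defaults, chosen once as
field-realistic and not revisited: additive noise SD 0.005 AU,
log-normal scatter SD 0.05, order-2 baseline with coefficient SD 0.02 AU,
per-leaf-position amplitude factor SD 0.05 (a global developmental-stage
effect, matching the observation that leaf position affects spectra
without confounding regions). Class effects are amplitude factors and
centre shifts at named wavenumbers; the defaults echo the published
direction of findings (lower pectin/tannin bands and a +4 cm⁻¹ shift for
NEE, stronger amide bands for WS, lipid differences for NWE, one small
distinguishing tweak per site). Every spectrum draws from a counter-based
random substream of the master seed, so regenerating any single design row
is bit-identical to the full run. Ground truth (applied factors, baseline
coefficients, scatter, substream seed) is returned for recovery tests.

What the generator does **not** emulate: instrument line shape,
atmospheric compensation residuals, Mie scattering, detector drift, or
between-leaf biological covariance beyond the leaf-position factor. A
green synthetic test therefore establishes that the *algorithms* recover
known signal under realistic noise — not that any particular field result
is correct.

Two design points that surprised us and are worth recording:

* **Chance-level control needs a balanced design.** With the study's
  region sizes (720/360/180) an SVM on signal-free spectra sits near 57%
  CV accuracy by majority effects alone; "within 3·SE of 33.3%" is only a
  meaningful null on a balanced one-site-per-region subdesign
  (SRC/ESA/EDB), which is what the acceptance test uses.
* **The environmental null needs an effect-free world.** If site effects
  are injected, *any* site-constant covariate is decodable from the
  spectra (venetian folds all contain every site), so an "independent"
  covariate would still show high cross-validated R². The null-world
  spectra therefore carry no class effects; the positive control plants a
  covariate that is a linear functional of the site-mean spectra in an
  effect-carrying world.

## Numerical choices

* PCA via SVD; variance denominators n−1 throughout; explained variance
  as a percentage of total variance.
* PLS1 latent-variable count: argmin of CV RMSE, exact ties toward fewer.
* SMO stopping tolerance 1e-4 (KKT violation); Platt Newton iterations
  capped at 100 with backtracking line search.
* Rubber-band hull computed on the ascending orientation internally;
  orientation does not change a lower envelope.
* Degenerate inputs error loudly and early: zero-norm spectra, constant
  responses/columns, empty classes, unknown sites, unparseable labels
  (with row numbers), non-uniform grids.

## Known limitations

* The spectrum-level 70/30 split reproduces the published protocol but is
  optimistic about generalisation to new leaves or sites; use
  `group_by = "leaf"`-style splits for deployment estimates.
* Criterion-level reproduction of the published quality tables requires
  the deposited spectral archive, which cannot be redistributed here; the
  acceptance suite reports that criterion honestly as unmet.
* One PLS1 model per covariate; no multi-response PLS, O-PLS, kernel or
  sparse variants. No JCAMP-DX/OPUS binary readers.
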