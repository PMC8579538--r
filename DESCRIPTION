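Package: ftirprint
Title: Chemometric Classification and Biomarker Discovery for ATR-FTIR
    Plant Spectra
Version: 0.1.0
Authors@R:
    person("Ftirprint", "Developers", email = "ftirprint@example.org",
           role = c("aut", "cre"))
Description: Tools for discriminating plant material by geographic origin
    from attenuated total reflection Fourier-transform infrared (ATR-FTIR)
    leaf spectra. Implements the standard chemometric workflow: fingerprint
    region selection, Savitzky-Golay derivative smoothing, vector
    normalisation and rubber-band baseline correction; principal component
    analysis, PCA-LDA classification by Mahalanobis distance, and
    soft-margin support vector machines with a radial basis function kernel
    solved by sequential minimal optimisation; venetian-blinds
    cross-validation, stratified external test splits and per-class quality
    parameters; spectral biomarker extraction from
    difference-between-mean-support-vector spectra with literature-based
    wavenumber assignment; and partial least squares regression of spectra
    against soil and climate covariates, with Kruskal-Wallis / rank-LSD
    group comparison and compact letter displays for soil traits. A
    hierarchical synthetic spectrum generator with known injected class
    effects supports end-to-end validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
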