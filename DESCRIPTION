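Package: sersdecomp
Title: Amino-Acid Composition Decomposition from SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the amino-acid composition of peptide and
    protein samples from surface-enhanced Raman spectroscopy (SERS) spectra.
    Provides a calibrated synthetic SERS spectrum generator for the 20
    canonical amino acids, the standard spectral preprocessing chain
    (asymmetric-least-squares background subtraction, Savitzky-Golay
    smoothing, min-max normalization, peptide-band masking, signal-to-noise
    filtering), 3-D t-SNE embedding with cluster-separability diagnostics, a
    small transformer encoder classifier over 1117-channel spectra, and the
    reinterpretation of its averaged class probabilities as composition
    estimates, together with MSE/RMSE/NRMSE and coefficient-of-variation
    evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    signal,
    cluster,
    mclust,
    pracma,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
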