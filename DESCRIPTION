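Package: spectraforest
Title: Surrogate Minimal Depth Variable Selection and Co-Occurrence Mapping for SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-class surface-enhanced Raman scattering (SERS)
    datasets: vector normalization, no-signal filtering, band-occurrence
    profiles and wavenumber binning; classification forests with surrogate
    splits fitted in C++; surrogate minimal depth (SMD) variable importance
    with a shadow-variable selection threshold; mean adjusted agreement (MAA)
    variable relations rendered as spectrally resolved co-occurrence maps;
    PCA eigenspectra; a synthetic SERS spectrum generator with planted
    discriminative bands and co-occurrence groups; and a seeded, manifest-
    checked analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
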