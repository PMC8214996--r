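Package: pastage
Title: Staging Tumor Progression from Photoacoustic Time-Domain Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for classifying stages of
    tumor progression from ex vivo time-domain photoacoustic spectra.
    Implements spectral pre-processing (detrending, polynomial baseline
    correction, background subtraction, max-absolute normalization) and
    region-of-interest selection; label-preserving amplitude-rescaling
    augmentation; a periodized Daubechies-6 wavelet packet decomposition with
    per-subband energy accounting and exact reconstruction; minimal-redundancy
    maximal-relevance (mRMR) selection of approximation-band coefficients; and
    multi-class support vector machine evaluation (RBF, polynomial, linear
    kernels) under repeated stratified hold-out with per-class sensitivity and
    specificity reporting. A seeded hierarchical generator of synthetic
    photoacoustic spectra emulates the five-time-point study design so every
    stage can be exercised and benchmarked without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
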