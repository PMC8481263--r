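Package: pgsrange
Title: Prompt Gamma Spectroscopy Range Verification with a Silicon-Loaded
    Endorectal Balloon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis pipeline for prompt gamma spectroscopy
    (PGS) verification of single-spot proton ranges in a prostate phantom
    carrying an endorectal balloon filled with a silicon-dioxide/water
    mixture. Provides a synthetic campaign generator (2048-bin energy
    spectra with Poisson counting noise, Cauchy-Lorentz de-excitation
    lines, pulse traces and time-of-flight event streams), trace and
    spectral processing (exponentially modified Gaussian pulse fits,
    Savitzky-Golay smoothing, SNIP baseline estimation, energy
    calibration, dead-time correction), background-suppression
    bookkeeping (TOF and BGO anticoincidence layers), a nested
    Cauchy-Lorentz F-test for detecting the 1.78 MeV silicon
    de-excitation line, and a linear peak-area-to-range model with
    inverse prediction and RMSE reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
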