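Package: compflux
Title: Compartmentalized 13C Metabolic Flux Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 13C metabolic flux analysis (13C-MFA) of mammalian
    cells with a compartmentalized (cytosol/mitochondrion) atom-transition
    network model. Provides forward simulation of steady-state mass
    isotopomer distributions by elementary metabolite unit (EMU)
    decomposition with a brute-force positional-isotopomer oracle,
    natural isotope-abundance correction of GC-MS measurements,
    uptake/secretion rate estimation from spent-media time courses for
    proliferating and quiescent cultures, variance-weighted least-squares
    flux estimation with multi-start optimization, chi-square
    goodness-of-fit testing and profile-likelihood confidence intervals,
    model-free tracer ratio statistics, and a synthetic parallel-labeling
    study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
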