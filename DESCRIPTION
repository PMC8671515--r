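Package: lhcmr
Title: Latent Heritable Confounder Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous estimation of bi-directional causal effects,
    direct heritabilities and latent heritable-confounder effects for a
    pair of complex traits from genome-wide association summary
    statistics. The bivariate likelihood of observed marginal effect
    estimates is evaluated by Fast Fourier Transform inversion of its
    closed-form characteristic function under a spike-and-slab genetic
    architecture and a spike-and-slab approximation of local linkage
    disequilibrium, and maximised in two steps with multi-start
    box-constrained optimisation. Includes a summary-statistics
    simulator covering sample overlap, non-Gaussian effect sizes and
    multi-confounder scenarios, block-jackknife standard errors, and
    genetic-correlation decomposition into confounder- and causal-effect
    driven components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
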