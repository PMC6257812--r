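Package: navadapt
Title: Variance Adaptation in Navigational Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying adaptation to stimulus variance in behavioral
    reverse-correlation experiments on larval Drosophila navigation. Generates
    the stochastic stimulus classes used in such experiments (reflected Brownian
    intensity walks, uncorrelated random levels, correlated multisensory pairs,
    sinusoidal gas backgrounds), simulates populations of larvae whose turn
    decisions follow an adaptive Linear-Nonlinear-Poisson cascade, estimates
    linear kernels by turn-triggered averaging with hierarchical bootstrap
    uncertainty, fits static and rescaling turn-rate models by maximum
    likelihood with BIC and jackknife comparison, tracks the time-varying input
    gain with a recursive Bayesian grid filter (1D and 2D), computes
    Bayesian-optimal online variance estimates with a diffusive prior, and
    compares additive and multiplicative models of multisensory integration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
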