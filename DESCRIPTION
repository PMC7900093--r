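Package: snailtrail
Title: Continuum and Agent-Based Models of Angiogenic Sprouting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing continuum descriptions of angiogenic sprouting
    with the lattice agent-based model that underlies them. Implements the
    snail-trail partial differential equation system (stalk production
    proportional to the magnitude of the net tip-cell flux, with the kappa
    correction factor), the coarse-grained Pillay system derived from a biased
    random walk with anastomosis, a stochastic lattice simulator of that walk
    with ensemble column-averaging, the shared leading-order asymptotic
    reduction in a frame moving with the chemotactic drift, and the early-time
    self-similar tip-cell profiles. Comparison machinery covers normalized
    pointwise-difference curves, pulse-peak and half-maximum wave-speed
    estimation, log-log power-law decay fits, and nonlinear least-squares
    calibration of branching and anastomosis parameters against ensemble data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
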