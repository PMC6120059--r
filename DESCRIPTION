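Package: slotcap
Title: Self-Consistency Analysis of Discrete-Resource Models of Visual Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing the internal consistency of discrete-resource
    (slot) models of visual working memory from continuous-report data. Fits
    the two-component circular mixture model (von Mises recall plus uniform
    guessing) by expectation-maximization, derives two capacity estimates per
    subject -- one from guessing frequency (K_Pm) and one from the plateau in
    recall variability (K_SD) -- and tests their correspondence with
    equality-versus-regression F tests, BIC differences and Pearson
    correlations. Includes Spearman's correction for attenuation with
    bootstrap reliabilities, a Bayesian hierarchical bivariate-normal model of
    the two estimates, and generative simulators (slots-plus-averaging and a
    doubly stochastic Gamma-precision hybrid) with a Monte Carlo engine for
    the self-consistency prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    rjags,
    coda
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
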