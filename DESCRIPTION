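Package: occamfia
Title: Geometric Bayesian Model Selection and Simplicity Preferences in
    Perceptual Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying Occam's razor as statistical model selection
    in two-alternative perceptual decisions. Candidate explanations are
    represented as geometric manifolds of 2D Gaussian centers (points,
    segments, circular arcs); the package computes exact Bayesian model
    evidence by quadrature under the Jeffreys prior and its Fisher
    Information Approximation (FIA), split into dimensionality, boundary,
    volume and robustness penalties, including a boundary factor for
    maximum-likelihood estimates that sit on the edge of the parameter
    domain. It also generates calibrated psychophysical task variants,
    simulates families of observers (maximum-likelihood, FIA, exact Bayes,
    posterior-sampling, and noise-integration-noise), estimates per-subject
    sensitivities to each complexity term with hierarchical Bayesian
    logistic regression (via JAGS), and builds fully synthetic cohorts for
    end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
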