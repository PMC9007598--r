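Package: isocomb
Title: Confidence-Level Response Surfaces for Combination-Therapy Dose Finding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Efficient characterization of combination-therapy dose-response
    under inter-individual variability and parameter uncertainty. Provides a
    hierarchical two-level Monte-Carlo population simulator for nonlinear
    mixed-effects PK/PD models, an adaptive dyadic grid-refinement algorithm
    (fastIsoboles) that locates the effective isobole -- the curve of minimum
    dose combinations reaching a prespecified efficacy target -- with a
    fraction of the simulations needed by a full grid scan, and an
    aggregation algorithm (aggregateIsoboles) that converts an ensemble of
    effective isoboles into a confidence-level response surface and
    confidence-level isoboles. Includes an ODE-based malaria-like PK/PD
    testbed model, analytic fixture surfaces with closed-form isoboles, and
    config-driven pipeline orchestration with delimited-text outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    MASS,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
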