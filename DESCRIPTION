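Package: ornacost
Title: Cost Functions of Purely Sexual Ornaments with Compensatory Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how compensatory traits shape the cost
    function measured in ornament-manipulation experiments. Implements
    bivariate quadratic (Lande-Arnold) performance surfaces and the
    one-dimensional cost curve induced by reducing an ornament while the
    compensatory trait stays fixed; locates the evolved phenotype under an
    added linear sexual-selection surface; solves a discrete
    survive-then-reproduce game for a balancing-toy model of ornament and
    compensation; generates synthetic manipulation-experiment tables from a
    calibrated torque-balance simulator; and analyses such tables with
    replicate averaging, ANOVA-based repeatability, and a Gibbs-sampled
    Bayesian linear mixed model with random individual intercepts,
    convergence diagnostics and posterior cost-shape verdicts.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
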