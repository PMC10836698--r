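Package: betaforest
Title: Forest-Plot Variants for Large Ensembles of Standardized Regression
    Coefficients
Version: 0.1.0
Authors@R:
    person("betaforest", "maintainers", email = "maintainers@betaforest.invalid",
           role = c("aut", "cre"))
Description: Fits grids of single-predictor linear models (plain, weighted,
    and school-clustered random-intercept variants), reports standardized
    slopes with Wald confidence intervals, pools plausible-value fits with
    Rubin's rules, condenses each domain-by-predictor cell to a beta-range
    summary, and draws case-bootstrap distributions of standardized slopes.
    Renders three displays for regression ensembles: the beta-range forest
    plot, the bootstrap ridgeline plot, and the bootstrap violin plot.
    Includes simulators for correlated truncated multivariate-normal athlete
    data and hierarchical assessment data with plausible values, sampling
    weights, and school clustering, plus a pipeline command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    lme4,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
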