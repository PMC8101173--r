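Package: hazoptim
Title: Optimal Fitting of Multiplicative and Additive Hazards Regression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting multiplicative (Cox-family) and additive
    (Aalen/Lin-family) hazards regression models optimally. Implements the
    Cox partial-likelihood machinery with time-varying coefficients and
    non-log-linear functional forms, Aalen's nonparametric least-squares
    additive model, the Lin-Ying constant-coefficient additive model,
    Schoenfeld and martingale residual diagnostics, jackknife
    pseudo-observations of survival with cloglog and scaled-log transformed
    diagnostic curves, stratified martingale-residual-process goodness-of-fit
    checks with wild-bootstrap confidence bounds and chi-square tests, Arjas
    observed-versus-expected plots, and two step-by-step strategies that
    iterate these diagnostics to select functional forms and time-varying
    effect structures. Includes seeded generators of synthetic right-censored
    survival data with multiplicative or additive covariate effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
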