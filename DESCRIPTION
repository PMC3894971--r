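Package: feno2c
Title: Two-Compartment Model Parameter Estimation for Multiple-Flow Exhaled
    Nitric Oxide
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of the physiologic parameters of the two-compartment
    model of nitric oxide exchange in the lower respiratory tract (alveolar NO
    concentration, maximum airway NO flux, and airway tissue diffusing
    capacity) from fractional exhaled NO (FeNO) measured at multiple
    exhalation flow rates. Implements the family of estimators compared in
    the multiple-flow FeNO literature: first-order (linP, linT) and
    second-order (quadP, quadT) ordinary-least-squares approximations with
    delta-method standard errors, direct nonlinear least squares on the
    natural and log scales (nonLin, nonLinLog) and a constrained variant
    (nonLinLogC), the iterative three-flow Hogman-Merilainen algorithm (HMA),
    and back-diffusion-adjusted estimators (Condorelli, Kerckx). Also
    provides a heteroscedastic synthetic-data generator for the standard
    four-flow study design and a Monte Carlo study runner computing estimator
    bias, confidence-interval coverage, and model diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
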