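Package: glucodyn
Title: Modelling Blood-Glucose Dynamics in Glucose and Insulin Tolerance Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits a damped second-order linear response model to blood-glucose
    curves from glucose (GTT) and insulin (ITT) tolerance tests by bounded
    multi-start nonlinear least squares, and extracts the derived curve
    characteristics (peak or nadir, inflection time and extremal rate,
    stabilized glucose, oscillation period, model AUC). Also provides the
    conventional analysis arm (trapezoidal AUC, Shapiro-Wilk screening,
    Mann-Whitney group comparison with Bonferroni correction, glycemic-band
    classification) and a protocol-faithful synthetic rat-cohort simulator,
    including biphasic contaminant curves, for validating the whole pipeline
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
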