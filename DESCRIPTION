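Package: kicer
Title: Reference-Tissue Patlak Analysis and Simulation of an FDOPA
    Pharmacological Challenge Study
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates dynamic FDOPA PET time-activity curves from an
    irreversible two-tissue compartment model on realistic frame schedules,
    estimates striatal dopamine synthesis capacity (the influx constant
    Ki_cer) by reference-tissue Patlak graphical analysis, and generates
    two-scan subject cohorts with a latent set-point regulation model so
    that the full inferential battery of a pharmacological challenge study
    (percent change, correlations, paired and summary t-tests, intraclass
    correlation and test-retest variability, Lilliefors normality, Levene's
    test, the group-by-change repeated-measures ANOVA interaction, the
    baseline-by-group interaction regression, and the Fisher r-to-z
    comparison of correlations) can be exercised, calibrated for type-I
    error and power, and checked for regression-to-the-mean artefacts.
    Includes analytic and estimator-based propagation of fractional changes
    in the trapping rate k3 to the influx constant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    deSolve,
    nortest,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
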