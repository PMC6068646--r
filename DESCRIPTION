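Package: hgkrige
Title: External-Drift Kriging and Measurement-Error Regression for Soil
    Mercury Exposure Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geostatistical exposure assessment for residential soil mercury
    contamination. Predicts log10 soil mercury concentrations at residence
    locations by external-drift (universal) kriging with a drift that is a
    function of log10 distance to a contaminating canal, estimating the
    stable exponential covariance (sill, nugget, range) by restricted
    maximum likelihood. Validates predictions by k-fold cross-validation,
    then regresses human-biomonitoring mercury outcomes (urine, hair) on
    measured or kriging-predicted soil values with a family random
    intercept, including a Berkson measurement-error variant that
    propagates kriging prediction uncertainty into the health regression.
    A synthetic-data generator reproduces the statistical structure of the
    study design so every stage runs without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
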