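Package: pigfcr
Title: Feed-Efficiency Phenotyping from Automatic Feeder Data in Growing Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control, cleaning and standardization of automatic
    feeding station (AFS) visit records for growing pigs, and prediction of
    feed conversion ratio (FCR) from short measurement windows. Implements
    eight visit-level quality-control rules on feed intake, occupation time
    and feed rate; per-animal robust regression of body weight on day and a
    three-parameter logistic population growth model; mixed-model imputation
    of outlying single-visit intakes; standardization of cumulative feed
    intake (CFI) to the 30-120 kg body-weight range via CF-ratio and
    intercept-based (A) correction formulas; sliding-window analysis of
    stage-specific FCR informativeness with two-segment breakpoint selection
    of the optimal measurement range; and a Bayesian ridge regression
    (evidence maximization) predicting 30-120 kg CFI from a short window.
    Includes a calibrated visit-level synthetic herd generator with ground
    truth so the full pipeline is testable without proprietary feeder data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
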