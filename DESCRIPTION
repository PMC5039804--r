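Package: predext
Title: Updating Clinical Prediction Models with New Markers
Version: 0.1.0
Authors@R:
    person("predext", "maintainers", email = "predext@example.org", role = c("aut", "cre"))
Description: Strategies for extending an existing logistic-regression risk
    model with a newly measured marker when the marker is available only in a
    (possibly small) separate dataset: model revision with extension,
    recalibration, model revision with heuristic shrinkage, recalibration with
    extension, Bayes-rule updating via conditional likelihood ratios (full and
    parsimonious variants), and a combine-and-impute approach that stacks the
    development and marker sets, multiply imputes the systematically missing
    marker, and pools with Rubin's rules.  Includes validation metrics
    (concordance statistic and calibration slope), a parametric generator of
    screening-cohort-like populations under a logistic or a conditional
    likelihood ratio truth model, and a replicated simulation framework to
    compare the strategies across development/marker sample-size scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
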