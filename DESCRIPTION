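Package: odorthresh
Title: Canine Odor Detection Threshold Estimation from Adaptive Staircase Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating animal odor detection limits from
    three-alternative forced-choice (3-AFC) olfactometer sessions run with a
    3-down-1-up adaptive staircase. Provides a flow-based air-dilution model
    for olfactometer concentration ladders, a staircase state machine with
    floor, time-cap and welfare termination rules, geometric-mean threshold
    estimation with floor/failure imputation, behavioral covariate extraction
    (search latency, inter-box interval, subcutaneous temperature), linear
    mixed-effects analysis of environmental-condition and acclimatization
    effects with Wald chi-square tests and post-hoc contrasts, volatile
    organic compound (VOC) odor-availability regressions, and a synthetic
    psychometric-observer generator for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    car,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
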