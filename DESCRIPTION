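Package: rnmconcord
Title: Semi-Quantitative Regulatory Network Simulation and Model-Experiment Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-quantitative regulatory network models (RNMs) of
    cartilaginous cells: signed weighted networks with continuous-logic
    dynamics, sustained node clamping, attractor ensembles from random initial
    conditions, pro-anabolic/pro-catabolic steady-state classification, and
    bisection scans for critical clamp levels. Includes a multiplex
    immunoassay (Luminex-style) calibration pipeline (blank subtraction,
    five-parameter logistic standard curves, limit-of-quantification
    normalization, reference subtraction) and semi-quantitative
    model-experiment concordance statistics (normalized mean absolute
    deviation and per-protein normalized root squared error), plus seeded
    generators for benchmark networks and synthetic secretome panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
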