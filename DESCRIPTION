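Package: calcikin
Title: Bayesian Inference of Intracellular Calcium Kinetics from
    Fluorescence Imaging Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation of Li-Rinzel-type intracellular calcium
    dynamics in astrocytes, a saturating fluorescent-indicator observation
    model, and variational Bayesian (Laplace) inversion of per-ROI calcium
    imaging traces to estimate molecular kinetic parameters (SERCA, IP3
    receptor, ER leak, and IP3 turnover rates). Includes a seeded synthetic
    trace generator with known ground truth, batch inversion over cohorts,
    group-level summary statistics, and Kolmogorov-Smirnov group
    comparisons.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
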