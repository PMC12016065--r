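Package: wkdeclock
Title: Weighted 2D Kernel Density Epigenetic Age Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds probabilistic epigenetic age predictors from DNA
    methylation beta-value matrices. For every age-associated CpG site a
    two-dimensional kernel density over chronological age and methylation
    level is estimated on a fixed 101x101 grid; the per-sample density rows
    are combined, with per-CpG weights tuned by a genetic algorithm, into an
    age-probability distribution whose mode is the predicted age. The
    standard deviation of the unweighted probability distribution (the
    variation score) quantifies heterogeneity of age-associated methylation
    within a sample. Includes age-correlation signature selection with
    uniform-age subsampling, linear-regression comparator clocks, a
    synthetic methylation cohort simulator with batch and disease effects,
    portable model serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
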