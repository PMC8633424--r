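Package: metacogsim
Title: Simulation and Reliability Analysis of Metacognitive Performance Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well confidence ratings track decision
    accuracy. Implements a generative signal-detection model of a binary
    choice task in which reported confidence is corrupted by metacognitive
    noise (a mode-parameterized Beta distribution), the standard family of
    metacognitive performance measures (type 1 d-prime, AUROC2, maximum
    likelihood meta-d-prime, M_diff, M_ratio and its excluded, bounded,
    logarithmic and hierarchical variants), test-retest reliability
    statistics (Pearson correlation and the normalized mean absolute error),
    and simulation experiments that characterize the type 1 performance
    dependence and test-retest reliability of these measures. Also reads
    trial-level confidence CSV files in the Confidence Database convention
    and applies the matching preprocessing and inclusion rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang
Suggests:
    rjags,
    coda,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
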