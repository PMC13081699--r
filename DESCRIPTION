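Package: fcage
Title: Brain-Age Prediction from Functional Connectivity and Reading-Group
    Bias Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts chronological age from functional-connectivity (FC)
    features with a permutation ensemble of principal-component analysis
    followed by linear support-vector regression, back-projects model
    weights to individual connections with permutation-null significance
    at the edge, region, and network levels, and tests reading-group bias
    in the brain-age gap with repeated-measures ANCOVA and continuous
    reading-skill regressions. Includes a synthetic cohort and
    connectivity generator that emulates a large developmental sample
    (ages 6-21, three reading-skill groups) so the full pipeline is
    testable without access-restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
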