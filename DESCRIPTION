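Package: itdepot
Title: Tissue Pharmacokinetics and Efficacy Analysis for Long-Acting
    Intratumoral Depots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative toolkit for long-acting intratumoral microsphere
    depots that release drug through beta-eliminative linkers. Models
    first-order, pH-dependent linker release and the depot-to-tissue
    exposure cascade; implements the ratio-metric (internal stable-marker)
    estimator of tissue release and clearance half-lives together with a
    synthetic biopsy-data generator for validating it; and analyses tumor
    growth inhibition by fractional AUC, Bliss-style combination additivity
    indices, and time-to-volume-threshold survival.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
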