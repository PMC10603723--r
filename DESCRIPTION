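Package: fishration
Title: Daily Ration, Growth and Ecological Conversion Efficiency from
    Gastric Evacuation Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates fish bioenergetic indices from destructive
    stomach-sampling designs: the instantaneous gastric evacuation rate
    from log-linear regression of stomach contents on time, the Eggers
    daily ration (Cd = 24 * S * R), the daily growth rate from weight
    regressions, and the gross (ecological) conversion efficiency
    Eg = 100 * Gd / Cd. A temperature-by-body-weight efficiency surface
    is completed from sparse determined cells by two-pass natural cubic
    spline interpolation, with iso-temperature profile extraction.
    Includes an individual-based simulator of evacuation trials, diel
    stomach-content sampling and temperature-by-weight group
    experiments with known ground truth for estimator validation, plus
    CSV readers/writers and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
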