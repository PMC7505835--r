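Package: retbench
Title: Retention Benchmarks for Salvage Logging via Mixed Rarefaction/Extrapolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how much of a naturally disturbed forest must be left
    unlogged to maintain a target fraction of the richness of species unique
    to the unlogged habitat. Implements sample-based (incidence) rarefaction
    and extrapolation with Chao2 estimation of undetected richness, a
    proportional mixture of two within-habitat curves under plot replacement
    with decomposition into unique and shared components, inversion of the
    normalized unique-richness curve into retention benchmarks, group
    summaries, and a beta regression with a spline smooth for time since
    disturbance. Includes a synthetic-data generator with analytic truth and
    exact and Monte-Carlo subsampling oracles so the full pipeline is
    testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
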