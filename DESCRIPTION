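Package: phasefluct
Title: Spatio-Temporal Fluctuation Maps and Fusion-Network Classification of
    Quantitative-Phase Cell Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts dynamic quantitative-phase (optical path delay) videos of
    single live cells into a morphology map and a spatio-temporal fluctuation
    map (radially averaged power spectral density over spatial frequency q and
    temporal frequency omega), reconstructs OPD maps from off-axis holograms,
    and classifies cells with single-, double- and triple-path fusion
    convolutional networks trained under a repeated-shuffle protocol. Includes
    a synthetic-data generator producing two-class cell-like OPD videos with
    class-dependent membrane-fluctuation statistics, so the full pipeline is
    testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
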