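Package: apdmapr
Title: Action Potential Duration Dispersion Mapping for Cardiac Optical Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of voltage-sensitive-dye optical mapping movies of the
    heart: per-pixel action potential duration (APD) mapping at a configurable
    repolarization level, windowed standard-deviation dispersion maps with
    threshold-based binarization and supra-threshold area quantification,
    connected-component island morphometry, spatial point-pattern statistics
    (quadrat variance-to-mean ratio, Clark-Evans nearest-neighbour index,
    Moran's I) with a uniform/random/clustered pattern classifier, dominant
    frequency and phase maps with phase-singularity detection, and a synthetic
    movie generator producing paced action-potential trains and reentrant
    spiral waves with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
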