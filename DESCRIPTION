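Package: dwcp
Title: Digital Whole-Community Phenotyping of Vegetation Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes community-level morphological and physiological
    parameters of vegetation plots from multispectral 3D point clouds, as
    produced by close-range laser triangulation canopy scanners. Covers
    point-cloud input/output (PLY and CSV), distance-attenuation correction,
    soil-plane calibration, plant/soil segmentation, 2.5D surface
    reconstruction, canopy height and light-penetration statistics,
    three-dimensional and projected leaf area, leaf angle and inclination,
    and multispectral vegetation indices (NDVI, NPCI, PSRI, greenness, hue).
    Includes a synthetic canopy-scanner simulator with analytic ground truth,
    community-weighted trait means, and random-forest classification of plots
    to provenance and land-use treatments with out-of-bag accuracy and
    variable importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    utils,
    grDevices,
    FNN,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    interp,
    yaml,
    optparse
Config/testthat/edition: 3
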