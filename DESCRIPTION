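Package: ricevor
Title: Rice Cluster Detection and Voronoi-Based Stand Uniformity from
    Nadir RGB Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates and evaluates the spatial uniformity of transplanted
    rice stands from nadir (UAV-style) RGB field images. Detects rice
    clusters (hills) with a colour-rule binarization followed by a
    morphological denoise/dilate/quantile-split/erode pipeline, assigns each
    cluster its occupied ground area as the Voronoi cell built from
    circumcenters of incident Delaunay triangles, and summarises stand
    evenness with a coefficient-of-variation heterogeneity index and its
    reciprocal uniformity index. Includes stochastic layout simulators
    (perturbed lattice, boundary-preserving omission, fully random) used to
    validate the index, a synthetic scene renderer with exact ground truth
    for end-to-end testing, detection-quality scoring, and gamma modelling
    of localisation errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
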