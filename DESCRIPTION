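Package: rootpouch
Title: High-Throughput 2D Root Phenotyping from Growth-Pouch Images
Version: 0.1.0
Authors@R: person("Pouch", "Phenomics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting root system architecture traits from
    two-dimensional images of plants grown in paper-based growth pouches.
    Provides a background-cleaning segmentation pipeline (lightness-channel
    thresholding in CIELAB space, connected-component labelling, and
    size/position filtering of non-root debris), skeleton-based measurement
    of seven root morphological traits (total length, surface area, volume,
    mean diameter, tip count, and diameter-class surface areas) and five
    architectural traits (width, convex area, solidity, depth index, and
    centre of projected mass), a parametric synthetic root-image generator
    with analytic ground truth for validating the pipeline, and supporting
    statistics: tip-count validation, broad-sense heritability from
    replicated genotype trials, and linkage-block-based Bonferroni
    thresholds for genome-wide association scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    stats,
    utils,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
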