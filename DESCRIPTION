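Package: foci3d
Title: Quantitative 3D Analysis of DNA Damage and Replication Foci
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection, segmentation, classification and spatial statistics
    for nuclear foci in calibrated multi-channel 3D confocal stacks.
    Implements prominence-based local-maxima detection as the conjunction of
    orthogonal 2D searches, iterative-flooding focus segmentation with
    physical volume and raw-image mean-intensity measurement, a bright/dim
    classifier for gamma-H2AX foci, nearest-neighbor distance analysis, and
    normalized Ripley K (L-function) auto- and cross-correlation with a
    Monte-Carlo complete-spatial-randomness reference inside the nuclear
    mask and per-distance significance testing. Ships a synthetic-image
    generator (ellipsoidal nuclei, two focus populations, configurable
    cross-channel colocalization and clustering, PSF blur, shot noise) with
    full ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, Spatial, Visualization
RoxygenNote: 7.3.3
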