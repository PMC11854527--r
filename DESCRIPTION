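Package: kinseg
Title: Consensus-Based Kinetic Segmentation of Grayscale Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of 2D grayscale images by evolving pixels
    as an interacting particle system under a two-bound (space and gray level)
    bounded-confidence rule with feature-dependent diffusion. The dynamics are
    simulated with a Direct Simulation Monte Carlo (Nanbu-Babovsky) scheme; the
    emergent spatial clusters are converted into a multilevel mask, binarized at
    a region-of-interest percentile threshold and morphologically refined. The
    package also provides a binary segmentation metric suite (Volumetric Dice,
    Surface Dice with boundary tolerance, Jaccard, precision/sensitivity and the
    F-beta measure) and seeded random-search calibration of the three model
    parameters against any of these metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    png,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Collate: 
    'kinseg-package.R'
    'AllClasses.R'
    'calibration.R'
    'cli.R'
    'clustering.R'
    'image.R'
    'kinetics.R'
    'mask.R'
    'metrics.R'
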