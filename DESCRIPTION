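Package: seedscore
Title: Image-Based Single-Seed Germination Scoring with k-Nearest Neighbours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores germination of individual seeds from time-series image tiles.
    Each tile is segmented by grey-level thresholding and 8-connected component
    labeling, the central seed object is described by 25 morphology and intensity
    features plus 1536 RGB and HSB colour-histogram features, features are min-max
    normalised and optionally reduced to principal components, and a Euclidean
    k-nearest-neighbour majority vote classifies each image as germinated or not
    while reporting a vote certainty. Includes an uncertainty-driven label
    amendment loop, per-seed ROC/AUC evaluation, and a synthetic seed-image
    generator that emulates radicle emergence, water-uptake swelling, mould and
    broken seeds so the whole pipeline can be exercised without a camera.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    grDevices,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
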