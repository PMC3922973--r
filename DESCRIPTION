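Package: whalesat
Title: Whale Detection in Very High Resolution Satellite Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting and counting large whales in very high
    resolution multispectral satellite imagery of calm coastal waters.
    Implements single-band histogram thresholding optimized by the ratio of
    multi-pixel to single-pixel connected components, unsupervised (k-means,
    ISODATA) and supervised (maximum likelihood) per-pixel classification
    baselines, whale-sized object extraction with size and shape filtering,
    three-class detection labelling (probable, possible, coastal-band only),
    and detection-evaluation metrics against manually digitized reference
    counts. Includes a synthetic scene generator that emulates the WorldView2
    band structure, including the water-penetrating coastal band, so the full
    pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
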