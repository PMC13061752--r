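Package: spikeletr
Title: Spikelet Detection and Counting from Point Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting and counting wheat spikelets in RGB
    spike images from minimal point annotations. Expert-clicked spikelet
    centers are converted into training targets (binary disc masks,
    normalized Gaussian density maps, or fixed-size square box labels),
    a compact fully-convolutional encoder-decoder network is trained with
    binary cross-entropy or Kullback-Leibler divergence losses under a
    reproducible augmentation recipe, predicted maps are decoded back to
    center coordinates, and predictions are scored with distance-threshold
    matching (precision/recall/F1 at a physical radius) and per-image
    counting errors (MAE/MAPE). A seeded synthetic spike-image generator
    with exactly known centers supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
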