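Package: projectomer
Title: Single-Neuron Projectome and Morphometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of whole-neuron morphologies (SWC
    reconstructions) registered to an annotated 3D region atlas: decomposition
    of axons into per-region arborizations, projection target calling with
    passing-fiber exclusion, targeting-probability and targeting-strength
    connectome matrices, laminar profiles, axon-cloud overlap scores from
    between- and within-class scatter matrices, kernel-density axon-cloud
    volumes, soma-to-centroid topography via principal-axis Spearman rank
    correlation, region hierarchy scores with feedforward/feedback
    classification of cell types, and morphometric feature extraction with
    hierarchical clustering and random-forest cell-type classification.
    Includes a synthetic-population generator with planted projection
    profiles, topographic gradients and hierarchies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    RNifti,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
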