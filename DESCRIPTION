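Package: pestscout
Title: Saliency-Based Localization and Convolutional Classification of Pest Insect Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale pipeline for localizing and classifying insect pests in
    field images. Images are over-segmented with a graph-based (minimum spanning
    tree) method, a global-contrast region-based saliency map is computed from
    quantized colour histograms with spatial weighting, and salient objects are
    refined by GrabCut foreground extraction, extended to square crops, and
    resized to a fixed input size. An AlexNet-family convolutional classifier is
    built declaratively, with layer-removal and width-reduction presets,
    parameter counting, stochastic-gradient training with momentum, weight decay
    and dropout, softmax and one-versus-all hinge losses, and mean-average-
    precision evaluation. Seeded synthetic scene and dataset generators make
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
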