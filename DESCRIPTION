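Package: szlayers
Title: Distance-Windowed Neural Network Layers and Parameter-Reduction
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Construction and analysis of distance-based weight windows
    (band, Gaussian, stripe, centered, random) for neural network layers,
    masked dense "schizophrenia connection" layers and channel-masked
    "schizophrenia convolution" layers with their sum-preserving
    renormalization, and the two intervention protocols used to study
    them: post-training ("disorganized") masking and in-training
    ("developmental") masking.  Includes a small seeded training engine,
    builders for the reference network configurations and reduced-scale
    variants, readers for the IDX and CIFAR-10 binary dataset formats, a
    synthetic image-classification generator for download-free
    experiments, and sweep plus rank-sum comparison utilities that
    regenerate error-versus-reduction curves at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
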