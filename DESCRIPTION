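Package: pepperFNF
Title: Flash-No-Flash Compositing and Color-Based Sweet Pepper Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Controlled-illumination imaging toolkit for greenhouse fruit
    detection. Implements flash/no-flash (FNF) pair identification in a
    frame stream and saturation-aware composite construction, an HSV
    color-blob sweet-pepper detector with morphological cleanup and
    minimum-size filtering, a cluster-aware precision/recall evaluation
    protocol with strict and flexible maturity schemes, a synthetic
    flash/no-flash greenhouse-scene simulator with per-pixel ground
    truth, and a command-line pipeline tying the stages into
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    igraph,
    png,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Visualization, Segmentation
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'imaging.R'
    'detector.R'
    'evaluation.R'
    'simulator.R'
    'io.R'
    'cli.R'
    'pepperFNF-package.R'
    'utils.R'
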