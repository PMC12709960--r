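Package: depthseg
Title: Depth-Guided Crop Segmentation from Monocular Depth Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for generating crop segmentation masks from single-channel
    depth maps produced by monocular depth estimation models. Implements three
    histogram thresholding strategies for pseudo-mask generation (Otsu's
    between-class variance criterion, the generalized histogram thresholding
    family, and a gradient-guided histogram thresholding pipeline robust to
    biased backgrounds), XOR-trimap two-stage self-training for pseudo-label
    distillation over a pluggable segmentation backend, depth-guided
    edge-preserving mask refinement (guided filter and joint bilateral
    filter), pooled mean intersection-over-union evaluation, and a seeded
    synthetic crop-scene simulator for end-to-end validation without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: ImageProcessing, Segmentation, Classification
RoxygenNote: 7.3.3
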