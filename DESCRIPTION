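Package: irplaque
Title: Label-Free Amyloid-Beta Plaque Detection in Hyperspectral Infrared Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly-supervised detection and segmentation of amyloid-beta
    plaques in quantum-cascade-laser infrared (QCL-IR) microscopy images of brain
    tissue. Provides a synthetic phantom generator (hyperspectral scenes with
    ground-truth plaque masks and paired pseudo-immunohistochemistry renderings),
    the immunohistochemistry mask preprocessing chain (contrast windowing, Otsu
    binarization, morphological cleaning, weak region-of-interest labeling), a
    comparative segmentation network (depth-reduced U-Net with a masked pooling
    neuron, trapezoidal transfer function and two-term weak-supervision loss,
    trained with RMSprop), per-epoch model selection by specificity, whole-slide
    tiled inference with max-merge stitching, pixel-level evaluation including the
    purification factor, and export of plaque-shaped polygons to laser-
    microdissection stage coordinates via a fitted two-dimensional Helmert
    (similarity) transform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
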