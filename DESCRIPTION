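Package: grassID
Title: Vision-Based Discrimination of Wheat and Grass Weed Seedlings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for differentiating wheat, annual
    ryegrass and brome grass seedlings from top-view colour images at the
    1-4 leaf stage. Segments the plant region by HSV hue thresholding,
    extracts eleven colour, shape and texture features (normalized colour
    factors and excess-colour indices, erosion-based width, the Waddle
    Disk Ratio, histogram uniformity and entropy), removes redundant
    features by a correlation filter, fits a Varimax-rotated principal
    component model on the correlation matrix, and discriminates species
    pairs with thresholds derived from group confidence intervals. Ships
    a synthetic seedling-image generator with ground-truth masks so the
    full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, FeatureExtraction, Segmentation, Visualization
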