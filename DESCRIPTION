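Package: cytocascade
Title: Nuclear Morphometry and Two-Level Cascade Classification for
    Cervical Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic detection of abnormal cervical epithelial cells in
    stained liquid-based-cytology images. Provides detail-preserving
    histogram equalization and median denoising, histogram-valley adaptive
    threshold segmentation of stain-dark nuclei, extraction of 28 nuclear
    features (20 morphologic, 8 first-order and co-occurrence texture), a
    two-level cascade classifier (gain-ratio decision tree for
    epithelial/lymphoid/neutrophil/junk rough classification followed by
    penalized logistic regression for normal versus abnormal epithelial
    cells), evaluation utilities (confusion matrices, precision/recall/F,
    ROC/AUC, cascade rate composition), and a seeded synthetic image
    generator with ground-truth masks for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
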