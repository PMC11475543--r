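Package: exmloc
Title: Nanoscale Receptor Localization Analysis for Expansion-Microscopy
    Capillary Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying receptor localization relative
    to the abluminal (collagen IV) surface of brain microcapillaries imaged by
    5x expansion microscopy. Provides a seeded synthetic-capillary image
    generator with ground truth, iteratively trained pixel classification for
    low signal-to-noise spot segmentation, anisotropic nearest-distance mapping
    between receptor and collagen IV signals corrected for the expansion
    factor, distance binning into abluminal and intracellular classes, nuclei
    based capillary typing and QC, and per-capillary two-way ANOVA with Tukey
    multiple comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    jsonlite,
    car,
    emmeans,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
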