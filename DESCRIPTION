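Package: SynoQuant
Title: Region-Stratified Quantification of Immunofluorescence-Stained
    Synovial Tissue Sections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-automated quantification of multi-channel
    immunofluorescence images of synovial membrane sections. Provides
    locally adaptive mean thresholding of fluorescence channels, pixel-level
    co-localization of binary marker masks, seed-constrained watershed cell
    masks, rasterization of manually delineated tissue regions (intimal cell
    layer and subintimal layers), and the derived histomorphometric metrics:
    marker-positive area fractions per region, co-localization ratios,
    intimal cell density, and vessel density. A synthetic tissue-section
    generator with known per-cell ground truth supports end-to-end
    validation, and a normality-gated statistics stage reproduces
    group-comparison reporting with below-limit-of-detection analyte
    handling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: ImageAnalysis, CellBiology, Software
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'RcppExports.R'
    'roi.R'
    'segmentation.R'
    'quantify.R'
    'scenario.R'
    'generate.R'
    'render.R'
    'io.R'
    'cohort.R'
    'stats-describe.R'
    'stats-compare.R'
    'stats-lod.R'
    'pipeline.R'
    'SynoQuant-package.R'
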