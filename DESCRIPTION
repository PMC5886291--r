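Package: seedHSI
Title: Single-Seed SWIR Hyperspectral Chemometrics for Green Coffee Beans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantitative chemical imaging of single green coffee
    beans from line-scan short-wave-infrared (SWIR, 980-2500 nm) hyperspectral
    images. Reads ENVI-style hypercubes, calibrates raw detector counts to
    reflectance with white/dark references and exposure-time correction,
    converts to absorbance, segments individual beans from a dark stage,
    applies spectral pre-treatments (SNV, MSC, Savitzky-Golay derivatives,
    de-trending), fits NIPALS PLS1 calibrations for sucrose, caffeine and
    trigonelline with segmented cross-validation, reduces models to a few
    diagnostic wavebands by regression-coefficient magnitude, and renders
    per-pixel concentration maps. Includes a ground-truthed synthetic scene
    generator emulating bean-shaped linear spectral mixtures with correlated
    per-bean concentrations, scatter distortion and detector noise.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    MASS,
    png,
    EBImage,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'envi.R'
    'calibrate.R'
    'segmentation.R'
    'preprocess.R'
    'pls.R'
    'crossval.R'
    'bands.R'
    'imaging.R'
    'components.R'
    'simulate.R'
    'fixtures.R'
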