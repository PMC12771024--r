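Package: morph3p
Title: Longitudinal Morphometry of Vessels and Amyloid Plaques in Three-Photon Image Stacks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel three-photon microscopy z-stacks
    of the mouse cortex: preprocessing (adaptive histogram equalization,
    spectral crosstalk removal, dura removal, depth normalization, denoising,
    motion assessment), vascular morphometry from binary vessel masks
    (skeletonization, per-segment diameter, length, tortuosity, total vascular
    volume, inter-vessel distance, Dice QC), amyloid-plaque segmentation by
    multilevel Otsu thresholding with area-based filtering and equivalent-sphere
    radii, plaque-to-vessel distance analysis, depth-resolved image-quality
    metrics (signal strength, signal-to-background ratio, FWHM), and
    nonparametric between-session statistics. Includes a two-channel synthetic
    phantom generator with exact geometric ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Visualization, Preprocessing
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'longitudinal_stats.R'
    'morph3p-package.R'
    'phantom.R'
    'signal_quality.R'
    'plaque_morphometry.R'
    'vessel_morphometry.R'
    'preprocess.R'
    'stack_io.R'
    'pipeline.R'
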