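Package: tendonSI
Title: Quantitative MRI Analysis of Tendon Lesions with Synthetic Phantom
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for region-of-interest based quantification of tendon
    lesions in low-field MRI slice stacks: signal-intensity standardisation
    against background and cortical-bone reference regions
    (signal-difference-to-noise ratio and relative signal intensity),
    maximum-inscribed-circle and central small-circle lesion ROIs via an
    exact Euclidean distance transform, lesion cross-sectional area and
    volume across examination time points, locally adaptive automated
    lesion segmentation inside a tendon ROI, trichrome-stain blue-pixel
    histology quantification, and method-comparison statistics (tie-aware
    Spearman rank correlation with exact permutation p-values, ratio-scale
    Bland-Altman limits of agreement on log-transformed data, and percent
    agreement for binary lesion detection). A synthetic phantom generator
    emulating limb cross-sections with cortical bone, superficial digital
    flexor tendon and hyperintense lesions provides ground truth so every
    pipeline stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'histology.R'
    'io.R'
    'lesion-geometry.R'
    'pipeline.R'
    'roi.R'
    'segmentation.R'
    'stats.R'
    'synthetic.R'
    'tendonSI-package.R'
    'utils.R'
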