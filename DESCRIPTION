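Package: retMosaic
Title: Photoreceptor Mosaic Morphometry for Two-Photon Retinal Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies photoreceptor (PR) mosaics in two-photon excitation
    fluorescence images of flat-mounted retinas: watershed-based cell
    segmentation with per-cell transversal-area measurement, cell density,
    neuroinflammation count and area fractions against a healthy-area
    threshold, Fourier (Yellott ring) inter-cell spacing estimation and the
    maximum anatomical resolving power of the mosaic. Includes a calibrated
    synthetic mosaic generator emulating control and diabetic rat retinas for
    validation and power studies, and an end-to-end reproducible study
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    nortest,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Segmentation
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'groupstats.R'
    'morphometry.R'
    'spacing.R'
    'segmentation.R'
    'synthetic.R'
    'pipeline.R'
    'retMosaic-package.R'
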