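Package: ppmfiber
Title: Polychromatic Polarization Microscopy Simulation and Collagen
    Fiber Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A forward physical model of polychromatic polarization
    microscopy (PPM) colour formation in birefringent specimens
    (Poincare-sphere retarder calculus, spectral polarization fan,
    circular analyzer, spectral-to-RGB camera integration), a seeded
    synthetic fiber-phantom generator with ground truth, the
    differential-image processing workflow (white balance,
    complementary-pair difference, monochromatic conversion, brightfield
    overlay), block-based collagen fiber orientation and alignment
    quantification via a structure-tensor estimator and axial circular
    statistics, and Bland-Altman method-agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    tiff,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'optics.R'
    'phantom.R'
    'pipeline.R'
    'fibermetrics.R'
    'agreement.R'
    'io.R'
    'cli.R'
    'ppmfiber-package.R'
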