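Package: pclstrain
Title: Strain Mapping of Contracting Airways in Precision-Cut Lung Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes dense displacement and Lagrangian strain fields from
    time-lapse bright-field movies of precision-cut lung slices (PCLS)
    undergoing bronchoconstriction.  Displacements between a reference frame
    and each frame of interest are estimated with a dense pyramidal optical
    flow and converted to Lagrangian strain tensors whose principal
    components are essentially radial and circumferential with respect to
    the airway lumen.  Provides lumen segmentation and ellipse fitting,
    circumferentially averaged strain profiles binned by distance to the
    airway, strain kymographs, and a spokes analysis that samples strain
    along rays normal to the lumen within angular sections.  Includes a
    synthetic contraction simulator with analytic ground-truth displacement
    and strain fields for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
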