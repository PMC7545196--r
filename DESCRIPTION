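Package: onsmorph
Title: Semi-Automated MRI Morphometry of the Optic Nerve and Sheath
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies optic nerve (ON) and optic nerve sheath (ONS)
    geometry from coronal T2-weighted MRI volumes and operator-picked
    centerlines. Implements centerline-based ON deviation (maximum
    orthogonal distance of the fitted nerve path from the chord joining
    the ON head to the point 20 mm posterior along the trajectory),
    adaptive-threshold contour segmentation with isoperimetric-quotient
    filtering, inter-slice contour interpolation at a fixed posterior
    offset, and cross-sectional area / equivalent-diameter computation.
    Includes a digital imaging phantom generator (tapering concentric
    tubes with partial-volume rendering and Rician noise) providing
    analytic ground truth, and reliability statistics (intraclass
    correlation, coefficient of variation, consensus differences) for
    repeated-measures validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, grDevices, utils, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
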