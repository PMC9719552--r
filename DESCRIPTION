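Package: magbead3d
Title: Defocus-Based 3D Tracking and Transport Modelling of Magnetic Microbeads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional trajectories of superparamagnetic
    microbeads from bright-field microscopy videos. The axial coordinate is
    inferred from image sharpness (Tenenbaum/Tenengrad gradient) calibrated
    against piezo-stage focus sweeps; lateral coordinates come from
    intensity-based detection and frame-by-frame linking. The package also
    models magnetophoretic "hopping" transport over a stripe-domain magnetic
    field landscape: stray fields of alternating head-to-head/tail-to-tail
    domain walls, trapezoidal external field pulses, and a quasi-static
    vertical force balance of magnetic, electrostatic double-layer,
    van der Waals and effective gravitational forces. A seeded synthetic
    microscopy benchmark with known 3D ground truth makes the full pipeline
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
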