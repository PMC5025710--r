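Package: cyclomap
Title: Cylindrically Symmetric Initial Models, Density Docking and Ring
    Geometry for Single-Particle Cryo-EM
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for low-resolution single-particle cryo-EM analysis of
    elongated ring-shaped particles: generation of a rotationally symmetric
    3D initial model from a single 2D side-view class average by rotation of
    its Fourier transform about the long axis, soft-edged reference cylinder
    models, raised-cosine low-pass filtering and resolution arithmetic,
    conversion of atomic models to simulated density, exhaustive rigid-body
    docking of multiple subunit copies by FFT cross-correlation, hexamer
    ring-geometry metrics (opening angle, axial rise, bending, section
    extents, axial gate state), gold-standard Fourier shell correlation, and
    a synthetic-data generator producing hexamer phantoms with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
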