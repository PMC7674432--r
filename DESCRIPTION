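Package: spotr
Title: Spectrum and Polarization Optical Tomography Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction toolkit for spectrum and polarization optical
    tomography (SPOT) microscopy. From six polarization-modulated
    structured-illumination raw images (three pattern directions, two
    pi-shifted phases) it computes optically sectioned intensity,
    emission-ratio (lipid polarity), polarization modulation-depth
    (lipid phase), and dipole-orientation maps. Includes a physics
    forward simulator of dipole emitters for end-to-end validation,
    bead-based channel registration and illumination flat-field
    calibration, HiLo optical sectioning, harmonic polarization
    analysis, an accuracy-analysis framework with a two-fluorophore
    resolution experiment and noise sweeps, and measurement utilities
    (polyline sampling, repeat-fluctuation acceptance, polarity-phase
    group ellipses and compartment classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
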