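Package: atraflux
Title: Steady-State Fluid and All-Trans Retinoic Acid Transport in the
    Choroid and Sclera
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves a one-dimensional, steady, two-layer porous-media model
    of fluid and all-trans retinoic acid (atRA) transport across the choroid
    and sclera of mouse and human eyes. Fluid flow follows Darcy's law with
    Starling filtration across the choriocapillaris wall and a Goldmann
    aqueous-humour balance that determines intraocular pressure
    self-consistently. Serum albumin and the atRA:albumin complex are
    transported by advection and diffusion, with choroidal atRA synthesis,
    transmural vessel leakage, and an induced CYP26 degradation sink in the
    sclera. Includes parameter presets with unit handling, calibration of
    uncertain rate parameters against physiological targets, an extended
    Fourier Amplitude Sensitivity Test (eFAST) for global sensitivity
    analysis, and synthetic-data generators for serum time courses and
    calibration targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
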