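Package: mnpkinetics
Title: Kinetic Analysis of Microfluidic Magneto-Nanosensor Binding Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyses multiplexed binding traces of
    protein-conjugated magnetic nanoparticles flowed over magneto-nanosensor
    arrays in microfluidic channels. Provides absorbance-based nanoparticle
    concentration calibration, reference subtraction and onset
    synchronization, exponential (Langmuir isotherm) binding-curve fitting,
    decoupling of bivalent association and dissociation rates by linear
    regression of observed rates on concentration, conversion of bivalent to
    monovalent dissociation constants via an avidity model, and
    transport-physics diagnostics (Stokes-Einstein diffusivity, Peclet and
    Damkohler numbers) to verify the reaction-limited regime assumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    minpack.lm,
    deSolve,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
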