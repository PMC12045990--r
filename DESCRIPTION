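Package: organoidmech
Title: Mechanics and Imaging Analysis of Brain Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the mechanics and structural organization
    of brain organoids. Implements standard-linear-solid (SLS) viscoelastic
    fitting of micropipette-aspiration creep tests, a diluted triangular
    fiber-network model with embedded area-elastic cells for tissue
    stiffness under uniaxial compression, an apparent-diffusion-coefficient
    (ADC) distribution pipeline for multi-b diffusion-weighted MRI, and
    Sholl-style radial profiling of collagen immunofluorescence, together
    with seeded synthetic-data generators that emulate each measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    tiff
Config/testthat/edition: 3
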