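Package: fusemotion
Title: Quantitative Analysis of Class II Fusogen Conformational Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the prefusion-to-postfusion
    conformational change of class II membrane fusogens such as the gamete
    fusogen HAP2. Decomposes rigid-body domain motion between two
    conformational states into a center-of-mass translation and an
    axis-angle rotation after superposition on a reference domain;
    synthesizes low-pass-filtered densities from atomic models and matches
    negative-stain 2D class averages against projection template banks by
    normalized cross-correlation; analyses SEC-MALS protein-conjugate data
    (glycoprotein plus detergent micelle) with weight-fraction mixing of
    refractive-index increments and extinction coefficients; and extracts
    melting temperatures from tryptophan fluorescence-intensity-ratio
    thermal unfolding curves. Includes seeded synthetic-data generators
    with known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    bio3d,
    Biostrings,
    EBImage,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
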