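Package: paleodiet
Title: Paleodiet Reconstruction from Amino Acid Isotope Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing marine versus terrestrial dietary
    protein from stable isotope measurements of bone collagen and plant
    tissue. Implements trophic position estimation from compound-specific
    delta15N of glutamic acid and phenylalanine, two-source and
    human-trophic-level marine-fraction mass balances with first-order
    error propagation, bulk collagen delta13C two-component mixing,
    essential amino acid delta13C fingerprinting with PCA grouping and a
    Bayesian (Dirichlet-prior) source mixing model, and marine-reservoir
    corrected radiocarbon calibration against diet-weighted mixtures of
    atmospheric and marine calibration curves. Includes a synthetic
    food-web generator for testing estimator calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
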