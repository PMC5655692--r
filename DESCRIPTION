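Package: triaxwall
Title: Triaxial Passive and Active Mechanics of the Coronary Artery Wall
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for triaxial (circumferential, axial, radial)
    passive and active coronary-artery wall mechanics. Implements the Fung
    exponential passive strain-energy function and an error-function active
    (smooth muscle) law, reduction of inflation-extension pressure-diameter-
    force records to mean-wall first Piola-Kirchhoff stresses, constrained
    estimation of material constants by Levenberg-Marquardt warm starts and
    a genetic algorithm, a protocol-faithful synthetic data generator, and a
    two-layer thick-wall cylinder model with opening-angle residual strain
    for transmural Cauchy stress distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
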