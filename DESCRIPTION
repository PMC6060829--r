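Package: circuniform
Title: Tests of Circular Uniformity and Monte-Carlo Power Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seven tests of departure from circular uniformity (Rayleigh,
    V, Kuiper, Watson U2, Rao spacing, Hermans-Rasson, and a data-driven
    smooth test after Bogdan) with a shared Monte-Carlo null-calibration
    backend, the f-fold symmetry transformation for mirrored multimodal
    data, samplers and densities for the circular distributions commonly
    used to benchmark these tests (uniform, von Mises, wrapped Cauchy,
    wrapped skew-normal, and finite von Mises mixtures), a bootstrap
    confidence interval for the mean direction, and a simulation engine
    that estimates type-I error and power over configurable parameter
    sweeps. Includes a command-line interface for testing angle files,
    simulating samples, and running power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
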