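Package: transenv
Title: Transmissibility Model with Environment for Transgenerational
    Transmitted Environmental Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based mixed models for non-genetic inheritance.
    Implements the transmissibility model, in which a global transmissible
    potential is passed from parents to offspring through estimable sire and
    dam path coefficients, and its extension with an environment-induced
    covariance between the transmissibility samplings of animals sharing an
    environment. Provides sparse construction of the transmission
    relationship matrix and its inverse, restricted maximum likelihood
    (REML) estimation of the path coefficients and variance parameters, a
    boundary likelihood-ratio test (50:50 chi-square mixture) for the null
    hypothesis of no transmitted environmental effect, a mirrored two-line
    experimental-design simulator, and an experiment runner for power and
    type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
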