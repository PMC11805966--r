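Package: compositeSEM
Title: Composites in Structural Equation Models via the
    Henseler-Ogasawara Specification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model composites (weighted linear combinations of observed
    variables) inside covariance-structure structural equation models
    using the Henseler-Ogasawara specification. Builds identified
    parameter tables for free-weight, unit-weight and relaxed variants
    as well as the classical one-step and two-step baselines, estimates
    them by normal-theory maximum likelihood on covariance input,
    recovers composite weights from the inverted loading matrix,
    computes delta-method standard errors and standardized solutions,
    and assesses global fit (chi-square, RMSEA, SRMR, CFI, TLI, AIC,
    BIC, SABIC) including nested chi-square difference tests. Includes
    a multivariate-normal synthetic-data generator and a Monte-Carlo
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    pracma,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
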