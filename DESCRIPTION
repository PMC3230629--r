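Package: fluxcompete
Title: Flux Response Coefficients for Molecular Competition Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical flux response coefficients for networks in which
    several molecular competitors (sigma factors, mRNAs) share a limiting
    target resource (RNA polymerase core enzyme, the ribosome pool).
    Closed-form response coefficients, ratio relations and ultrasensitivity
    criteria are computed directly from conserved-moiety amounts, with no
    kinetic constants required.  Two mechanistic ODE simulators -- an
    n-competitor mass-action binding model and a ribosome-traffic polysome
    model with hard-body steric exclusion -- provide independent
    finite-perturbation oracles.  A synthetic transcriptome generator
    supports genome-scale response-distribution analyses of translation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
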