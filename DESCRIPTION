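Package: msldiff
Title: Inference and First-Passage Times for the Multisigmoidal Logistic
    Lognormal Diffusion Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, maximum likelihood inference and first-passage-time
    analysis for the non-homogeneous lognormal diffusion process whose mean is
    a multisigmoidal logistic curve, a growth model in which the exponent of
    the logistic function is a polynomial, allowing several inflection points
    before saturation. Provides exact-transition path simulation, the
    closed-form likelihood of discretely observed sample paths, maximum
    likelihood estimation by a damped Newton-Raphson solve of the score system
    and by simulated annealing over a data-driven bounded parameter space,
    Fisher-information/delta-method confidence intervals, polynomial-degree
    selection by information criteria and the resistor-average
    (symmetrised Kullback-Leibler) distance, and approximation of the
    first-passage-time density through a constant boundary via the
    first-passage-time location (FPTL) function and a second-kind Volterra
    integral equation solved by the composite trapezoidal rule.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
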