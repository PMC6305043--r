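Package: cproptim
Title: Blood Gas Delivery Modelling and Optimization of CPR Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic steady-state model of total blood gas delivery
    (systemic oxygen delivery plus carbon dioxide delivery to the lungs)
    during cardiopulmonary resuscitation, expressed in terms of
    rescuer-dependent parameters (compression-to-ventilation ratio,
    compression time, ventilation time, tidal volume, inspired gas
    fractions), a patient-dependent maximum blood flow, and physiological
    constants. Provides bounded simulated annealing with Metropolis
    acceptance, a global and a sequential per-CPR-cycle optimization
    scheme over the rescuer parameters, an exhaustive grid-search oracle
    for validating the stochastic optimizers, patient-group sweeps with
    tidy trajectory reports, and a configurable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
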