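Package: c4leaf
Title: Steady-State Modelling of C4 Leaf Gas Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward simulation and inverse diagnostics for steady-state C4
    photosynthesis. Implements the enzyme-limited (PEP carboxylase and Rubisco
    kinetics with bundle-sheath CO2 and O2 diffusion) and electron-transport-limited
    (linear and cyclic electron flow with explicit ATP stoichiometry) assimilation
    rates, Arrhenius and Gaussian temperature scaling of the photosynthetic
    parameters, mesophyll-conductance coupling between intercellular and cytosolic
    CO2, back-calculation of the electron transport rate sustaining a measured
    assimilation rate, conversion of isotope-derived leakiness into C4-cycle fluxes,
    response-curve generation (A-Ci, light, temperature), synthetic gas-exchange
    data with additive Gaussian noise, and least-squares estimation of capacity
    parameters from measured curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
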