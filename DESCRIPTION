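Package: topt
Title: Temperature Optimum Analysis for Enzyme Catalysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the temperature dependence of enzyme-catalysed
    reactions whose rate optimum is not set by protein melting. Implements
    Eyring/Arrhenius analysis of temperature-resolved activation free energies
    with continuous-hinge breakpoint detection, a reversible-inactivation
    kinetic model v(T) = k_rxn(T)/(1 + K_inact(T)) fitted to continuous
    temperature-ramp assay traces by numerical integration and multi-start
    bounded least squares, Michaelis-Menten steady-state fitting, and
    molecular-dynamics trajectory post-processing (hydrogen-bond distance
    densities and per-residue backbone RMSF after rigid-body superposition).
    Seeded synthetic-data generators emulate every input the pipeline
    consumes. All user-facing functions take data frames and return tibbles;
    fitted objects support tidy(), glance() and autoplot().
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
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
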