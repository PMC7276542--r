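Package: thermocomm
Title: Thermodynamic Modelling of Microbial Community Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates population and metabolite dynamics of anaerobic microbial
    communities with a thermodynamic growth law: each population runs one or more
    catabolic pathways whose rates combine Monod kinetics with a thermodynamic
    inhibition factor, and whose biomass yield is derived dynamically from a Gibbs
    energy balance between catabolism, anabolism and a fixed dissipation term.
    Medium pH is obtained at every derivative evaluation by solving the solution
    charge balance, and volatile metabolites exchange between the liquid and a
    sealed headspace through two-film mass transfer with temperature-adjusted
    Henry constants. Includes hierarchical calibration of pathway minimum-energy
    thresholds against time-series observations, one-dimensional error-landscape
    sweeps, estimation of volumetric transfer coefficients from gas equilibration
    series, and generators for a sulfate-reducer/methanogen model community and
    synthetic observation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
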