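#' Model community configuration: sulfate reducer plus two methanogens
#'
#' Builds the full configuration for batch cultures of a lactate-oxidizing
#' sulfate reducer (`Dv`), a hydrogenotrophic methanogen (`Mm`) and a
#' hydrogenotrophic/acetoclastic methanogen (`Mb`) in a sealed anaerobic
#' tube: 5 mL liquid under ~12 mL headspace at 37 degrees C, 30 mM lactate
#' and 7.5 mM sulfate, simulated for 21 days.
#'
#' `Dv` carries three catabolic pathways (lactate fermentation, incomplete
#' lactate oxidation on sulfate, hydrogen oxidation on sulfate) with
#' dissipation energies -265.1, -228.2 and -362.1 kJ per C-mol biomass;
#' `Mm` carries hydrogenotrophic methanogenesis (-876.4); `Mb` carries
#' hydrogenotrophic (-1059.8) and acetoclastic (-268.3) methanogenesis.
#' Each population has one anabolic reaction producing the generic biomass
#' C1 H1.8 O0.5 N0.2 (formation energy -67 kJ mol^-1) from its carbon
#' source (lactate, CO2 and acetate respectively).
#'
#' Kinetic constants (`v_max`, `K_S`) are literature-plausible
#' order-of-magnitude defaults - they are stated assumptions of this
#' fixture, not measured values - and all minimum-energy thresholds default
#' to -40 kJ mol^-1 (the usual calibration start).
#'
#' @param cultures Subset of `c("Dv", "Mm", "Mb")`.
#' @param lactate,sulfate Initial concentrations, mol L^-1.
#' @param od600 Initial total-community optical density.
#' @param duration Horizon, h.
#' @param kLa Volumetric transfer coefficient applied to every exchanged
#'   gas, h^-1.
#' @param solver Optional solver setting overrides.
#' @return A `tc_config`.
#' @export
build_dv_mm_mb_system <- function(cultures = c("Dv", "Mm", "Mb"),
                                  lactate = 0.030, sulfate = 0.0075,
                                  od600 = 0.05, duration = 504,
                                  kLa = 2, solver = list()) {
  cultures <- match.arg(cultures, several.ok = TRUE)
  sp <- default_species()

  families <- list(
    acid_base_family("lactate", c("lactic_acid", "lactate"), 3.86),
    acid_base_family("acetate", c("acetic_acid", "acetate"), 4.76),
    acid_base_family("carbonate", c("CO2(aq)", "HCO3", "CO3"), c(6.35, 10.33)),
    acid_base_family("sulfide", c("H2S(aq)", "HS"), 7.05),
    acid_base_family("ammonium", c("NH4", "NH3(aq)"), 9.25)
  )

  # Henry solubilities at 298.15 K (mol m^-3 Pa^-1) and van 't Hoff
  # temperature coefficients (K), standard compilation values
  exchanges <- list(
    phase_exchange("H2(aq)", "H2(g)", kLa, 7.8e-6, 500),
    phase_exchange("CO2(aq)", "CO2(g)", kLa, 3.3e-4, 2400),
    phase_exchange("CH4(aq)", "CH4(g)", kLa, 1.4e-5, 1900),
    phase_exchange("H2S(aq)", "H2S(g)", kLa, 1.0e-3, 2100)
  )

  dv <- population(
    "Dv",
    pathways = list(
      catabolic_pathway(
        "lactate_fermentation",
        reaction(c("lactate" = -1, "H2O" = -2, "acetate" = 1, "H2(aq)" = 2,
                   "HCO3" = 1, "H+" = 1), reference = "lactate"),
        v_max = 0.5, K_S = c("lactate" = 1.3e-3),
        dG_min = -40, dG_met = -265.1),
      catabolic_pathway(
        "lactate_sulfate_respiration",
        reaction(c("lactate" = -1, "SO4" = -0.5, "acetate" = 1, "HCO3" = 1,
                   "H2S(aq)" = 0.5), reference = "lactate"),
        v_max = 1.0, K_S = c("lactate" = 1.3e-3, "SO4" = 2e-4),
        dG_min = -40, dG_met = -228.2),
      catabolic_pathway(
        "hydrogen_sulfate_respiration",
        reaction(c("H2(aq)" = -1, "SO4" = -0.25, "H+" = -0.5,
                   "H2S(aq)" = 0.25, "H2O" = 1), reference = "H2(aq)"),
        v_max = 1.5, K_S = c("H2(aq)" = 1e-6, "SO4" = 2e-4),
        dG_min = -40, dG_met = -362.1)
    ),
    anabolic = anabolic_reaction(
      # printed coefficients; carries a known ~0.05 C-mol rounding imbalance
      reaction(c("lactate" = -0.35, "NH4" = -0.2, "H+" = -0.1,
                 "biomass" = 1, "acetate" = 0.05, "H2O" = 0.4)),
      donor = "lactate")
  )
  mm <- population(
    "Mm",
    pathways = list(
      catabolic_pathway(
        "hydrogenotrophic_methanogenesis",
        reaction(c("HCO3" = -0.25, "H2(aq)" = -1, "H+" = -0.25,
                   "CH4(aq)" = 0.25, "H2O" = 0.75), reference = "H2(aq)"),
        v_max = 2.0, K_S = c("H2(aq)" = 6e-6),
        dG_min = -40, dG_met = -876.4)
    ),
    anabolic = anabolic_reaction(
      reaction(c("HCO3" = -1, "H2(aq)" = -2.1, "NH4" = -0.2, "H+" = -0.8,
                 "biomass" = 1, "H2O" = 2.5)),
      donor = "H2(aq)")
  )
  mb <- population(
    "Mb",
    pathways = list(
      catabolic_pathway(
        "hydrogenotrophic_methanogenesis",
        reaction(c("HCO3" = -0.25, "H2(aq)" = -1, "H+" = -0.25,
                   "CH4(aq)" = 0.25, "H2O" = 0.75), reference = "H2(aq)"),
        v_max = 1.0, K_S = c("H2(aq)" = 1e-5),
        dG_min = -40, dG_met = -1059.8),
      catabolic_pathway(
        "acetoclastic_methanogenesis",
        reaction(c("acetate" = -1, "H2O" = -1, "CH4(aq)" = 1, "HCO3" = 1),
                 reference = "acetate"),
        v_max = 0.25, K_S = c("acetate" = 3e-3),
        dG_min = -40, dG_met = -268.3)
    ),
    anabolic = anabolic_reaction(
      reaction(c("acetate" = -0.525, "NH4" = -0.2, "H+" = -0.275,
                 "biomass" = 1, "HCO3" = 0.05, "H2O" = 0.4)),
      donor = "acetate")
  )
  pops <- list(Dv = dv, Mm = mm, Mb = mb)[cultures]

  # anaerobic medium: Na-lactate + Na2SO4 + 30 mM NaHCO3 buffer,
  # ~2 mM Na2S reductant, ~5.6 mM NH4Cl nitrogen source, plus ~6.5 mM
  # chloride standing in for the HCl used to bring the medium to pH ~7.2
  sulfide0 <- 0.002
  ammonium0 <- 0.0056
  bicarb0 <- 0.030
  na0 <- lactate + 2 * sulfate + bicarb0 + 2 * sulfide0
  cl0 <- ammonium0 + 0.0065
  initial <- list(
    totals = c(lactate = lactate, acetate = 0, carbonate = bicarb0,
               sulfide = sulfide0, ammonium = ammonium0, SO4 = sulfate,
               "H2(aq)" = 0, "CH4(aq)" = 0, Na = na0, Cl = cl0),
    gas = c("H2(g)" = 0, "CO2(g)" = 0, "CH4(g)" = 0, "H2S(g)" = 0),
    od600 = od600
  )

  simulation_config(
    species = sp, families = families, exchanges = exchanges,
    populations = pops,
    geometry = phase_geometry(V_aq = 0.005, V_g = 0.012,
                              temperature = 310.15),
    initial = initial, duration = duration, solver = solver)
}

#' Synthesize noisy observations from a known ground truth
#'
#' Simulates the configuration under a supplied set of true minimum-energy
#' thresholds, samples the observed variables on a schedule, and applies
#' seeded multiplicative lognormal noise (median-unbiased: the log-scale
#' mean is zero).
#'
#' @param config A `tc_config`.
#' @param true_dgmin Named vector of `"<population>:<pathway>"` thresholds,
#'   kJ mol^-1, imposed before simulating.
#' @param times Sampling schedule, h (default daily for 21 days).
#' @param variables Observed variables (trajectory columns).
#' @param sigma Lognormal sigma of the multiplicative noise (0 = noise-free).
#' @param seed RNG seed.
#' @param trajectory Optional pre-computed noise-free trajectory for these
#'   parameters (skips the simulation; useful when drawing many noise
#'   realizations from one ground truth).
#' @return List with `observations` (tibble `time`, `variable`, `value`),
#'   `truth` (the imposed thresholds) and `trajectory` (the noise-free
#'   simulation).
#' @export
synthesize_observations <- function(config, true_dgmin = c(),
                                    times = seq(24, 504, by = 24),
                                    variables = c("lactate", "acetate",
                                                  "H2(g)", "CH4(g)"),
                                    sigma = 0.05, seed = 1L,
                                    trajectory = NULL) {
  stopifnot(sigma >= 0, all(times <= config$duration))
  for (nm in names(true_dgmin)) {
    config <- set_dgmin(config, nm, true_dgmin[[nm]])
  }
  traj <- trajectory %||% simulate_community(config)
  obs <- tidyr::expand_grid(variable = variables, time = times)
  obs$value <- purrr::pmap_dbl(obs, function(variable, time) {
    trajectory_at(traj, variable, time)
  })
  if (sigma > 0) {
    set.seed(seed)
    obs$value <- obs$value * rlnorm(nrow(obs), meanlog = 0, sdlog = sigma)
  }
  list(observations = obs[, c("time", "variable", "value")],
       truth = true_dgmin, trajectory = traj)
}

#' Gas equilibration fixture for transfer-coefficient estimation
#'
#' Emulates the headspace-flush experiment used to estimate `k_La`: the
#' liquid starts saturated with a dissolved gas, the headspace starts empty
#' (flushed with inert gas), and the headspace content is sampled as the two
#' phases re-equilibrate. Pure transfer dynamics; no reactions, no
#' speciation.
#'
#' @param kLa True transfer coefficient, h^-1 (> 0).
#' @param spec A [phase_exchange()] (its `kLa` is overridden by `kLa`).
#' @param geom A [phase_geometry()].
#' @param aq0 Initial dissolved concentration, mol L^-1.
#' @param times Sampling schedule, h.
#' @return List with `observed` (tibble `time`, `value` of headspace
#'   content), `spec`, `geom` and `initial` - the arguments [fit_kla()]
#'   expects.
#' @export
gas_equilibration_fixture <- function(kLa,
                                      spec = phase_exchange("H2(aq)", "H2(g)",
                                                            0, 7.8e-6, 500),
                                      geom = phase_geometry(0.005, 0.012,
                                                            310.15),
                                      aq0 = 4e-4,
                                      times = c(0, 1, 2, 4, 8, 24)) {
  stopifnot(kLa > 0)
  sp <- spec; sp$kLa <- kLa
  sim <- integrate_transfer(sort(unique(times)), aq0, 0, sp, geom)
  list(observed = tibble::tibble(time = sim$time, value = sim$gas),
       spec = spec, geom = geom, initial = c(aq = aq0, gas = 0))
}
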