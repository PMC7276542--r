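#' Declare a catabolic pathway
#'
#' @param name Pathway name (unique within its population).
#' @param rxn Catabolic [reaction()] normalized to 1 mol of its reference
#'   substrate (coefficient -1).
#' @param v_max Maximum catabolic turnover rate, mol_S (mol_X h)^-1.
#' @param K_S Named numeric vector of half-saturation constants, mol L^-1,
#'   one per limiting substrate. Exactly the named species enter the Monod
#'   product; water and the proton are never kinetic substrates.
#' @param dG_min Minimum energy threshold, kJ per mol of reference substrate
#'   (< 0); the calibratable parameter of the model.
#' @param dG_met Metabolic (dissipated) energy, kJ per C-mol of biomass (< 0).
#' @return An object of class `tc_pathway`.
#' @export
catabolic_pathway <- function(name, rxn, v_max, K_S, dG_min = -40, dG_met) {
  stopifnot(inherits(rxn, "tc_reaction"), !is.null(rxn$reference))
  stopifnot(v_max > 0, all(K_S > 0), dG_min < 0, dG_met < 0)
  if (any(names(K_S) %in% c("H2O", "H+"))) {
    abort("water and the proton cannot be kinetic substrates")
  }
  structure(list(name = name, rxn = rxn, v_max = v_max, K_S = K_S,
                 dG_min = dG_min, dG_met = dG_met),
            class = "tc_pathway")
}

#' Declare an anabolic reaction
#'
#' Normalized so that the biomass species carries coefficient +1; the
#' electron-donor coefficient magnitude `gamma_D` links the yield to the
#' catabolic draw.
#'
#' @param rxn Anabolic [reaction()] with biomass coefficient exactly +1.
#' @param donor Name of the electron-donor species in `rxn`.
#' @param biomass Name of the biomass species (default `"biomass"`).
#' @return An object of class `tc_anabolic`.
#' @export
anabolic_reaction <- function(rxn, donor, biomass = "biomass") {
  stopifnot(inherits(rxn, "tc_reaction"))
  if (!biomass %in% names(rxn$coeffs) || rxn$coeffs[[biomass]] != 1) {
    abort("anabolic reaction must produce the biomass species with coefficient +1")
  }
  if (!donor %in% names(rxn$coeffs) || rxn$coeffs[[donor]] >= 0) {
    abort("electron donor must be consumed by the anabolic reaction")
  }
  structure(list(rxn = rxn, donor = donor, biomass = biomass,
                 gamma_D = abs(rxn$coeffs[[donor]])),
            class = "tc_anabolic")
}

#' Declare a microbial population
#'
#' @param name Population name; its biomass pool is named `X_<name>`.
#' @param pathways List of [catabolic_pathway()] objects (>= 1).
#' @param anabolic The single [anabolic_reaction()] shared by all pathways.
#' @param k_d Linear decay coefficient, h^-1 (default 8.33e-4).
#' @return An object of class `tc_population`.
#' @export
population <- function(name, pathways, anabolic, k_d = 8.33e-4) {
  stopifnot(length(pathways) >= 1L, k_d >= 0,
            inherits(anabolic, "tc_anabolic"))
  pathways <- setNames(pathways, vapply(pathways, `[[`, "", "name"))
  structure(list(name = name, pathways = pathways, anabolic = anabolic,
                 k_d = k_d),
            class = "tc_population")
}

#' Dynamic catabolic stoichiometry factor
#'
#' Number of catabolic turnovers needed per C-mol of biomass formed to close
#' the energy balance: `(dG_met - dG_an) / dG_cat`.
#'
#' @param dG_met Dissipated energy per C-mol biomass, kJ mol_X^-1 (< 0).
#' @param dG_an Anabolic reaction energy, kJ mol_X^-1.
#' @param dG_cat Catabolic reaction energy, kJ mol_S^-1; must be negative
#'   (the factor is only meaningful for a running pathway).
#' @return lambda_cat, mol_S mol_X^-1.
#' @export
lambda_cat <- function(dG_met, dG_an, dG_cat) {
  if (dG_cat >= 0) {
    abort("lambda_cat is undefined for non-exergonic catabolism (dG_cat >= 0)")
  }
  (dG_met - dG_an) / dG_cat
}

#' Growth yield implied by the dynamic stoichiometry
#'
#' Total substrate drawn per C-mol biomass is the catabolic draw plus the
#' anabolic donor draw, so `Y = 1 / (lambda_cat + gamma_D)`.
#'
#' @param lambda Catabolic turnovers per biomass, mol_S mol_X^-1.
#' @param gamma_D Donor coefficient of the anabolic reaction, mol_S mol_X^-1.
#' @return Yield, mol_X mol_S^-1.
#' @export
growth_yield <- function(lambda, gamma_D) {
  denom <- lambda + gamma_D
  if (denom <= 0) abort("lambda_cat + gamma_D must be positive")
  1 / denom
}

#' Multiplicative Monod kinetic factor
#'
#' @param concentrations Named vector of substrate concentrations, mol L^-1.
#' @param K_S Named vector of half-saturation constants, mol L^-1.
#' @return F_D in `[0, 1]`.
#' @export
kinetic_factor <- function(concentrations, K_S) {
  missing <- setdiff(names(K_S), names(concentrations))
  if (length(missing)) {
    abort(sprintf("no concentration supplied for limiting substrate(s): %s",
                  paste(missing, collapse = ", ")))
  }
  s <- pmax(concentrations[names(K_S)], 0)
  prod(s / (K_S + s))
}

#' Thermodynamic inhibition factor
#'
#' `F_T = 1 - exp(min(0, dG_cat - dG_min) / (R T))`: exactly 0 once the
#' available energy falls to the threshold, approaching 1 far from
#' equilibrium.
#'
#' @param dG_cat Catabolic reaction energy, kJ mol_S^-1.
#' @param dG_min Minimum energy threshold, kJ mol_S^-1.
#' @param temperature Kelvin.
#' @return F_T in `[0, 1)`.
#' @export
thermodynamic_factor <- function(dG_cat, dG_min, temperature) {
  stopifnot(temperature > 0)
  1 - exp(min(0, dG_cat - dG_min) / (.RGAS * temperature))
}

#' Evaluate one pathway at a chemical state
#'
#' Computes the catabolic and anabolic energies from free (speciated)
#' concentrations, the kinetic and thermodynamic factors, the specific rate
#' `r = v_max F_D F_T`, and - when the pathway can run - the dynamic
#' stoichiometry factor and yield.
#'
#' @param pathway A [catabolic_pathway()].
#' @param anabolic The population's [anabolic_reaction()].
#' @param species_set Species tibble with formation energies.
#' @param concentrations Named vector of free species concentrations,
#'   mol L^-1.
#' @param pH Medium pH.
#' @param temperature Kelvin.
#' @param conc_floor Floor applied to concentrations entering ln Q.
#' @param thermodynamics If `FALSE`, force `F_T = 1` (forward-kinetics
#'   variant); the anabolic coupling then requires only `dG_cat < 0`.
#' @return A one-row tibble: `dG_cat`, `dG_an`, `F_D`, `F_T`, `rate`,
#'   `lambda`, `yield` (the latter two `NA` when the pathway is off).
#' @export
pathway_specific_rate <- function(pathway, anabolic, species_set,
                                  concentrations, pH, temperature,
                                  conc_floor = 1e-12, thermodynamics = TRUE) {
  act <- pmax(concentrations, conc_floor)
  dg_cat <- reaction_energy(pathway$rxn, species_set, act, pH, temperature)
  dg_an <- reaction_energy(anabolic$rxn, species_set, act, pH, temperature)
  fd <- kinetic_factor(concentrations, pathway$K_S)
  ft <- if (thermodynamics) {
    thermodynamic_factor(dg_cat, pathway$dG_min, temperature)
  } else 1
  rate <- pathway$v_max * fd * ft
  couple <- if (thermodynamics) ft > 0 else dg_cat < 0
  lam <- yld <- NA_real_
  if (couple && dg_cat < 0) {
    lam <- lambda_cat(pathway$dG_met, dg_an, dg_cat)
    if (lam > 0) yld <- growth_yield(lam, anabolic$gamma_D) else lam <- NA_real_
  }
  tibble::tibble(pathway = pathway$name, dG_cat = dg_cat, dG_an = dg_an,
                 F_D = fd, F_T = ft, rate = rate, lambda = lam, yield = yld)
}

#' Biochemical derivatives of a community at a chemical state
#'
#' Assembles `d[A]/dt = sum_i X_i sum_j r_ij (gamma_iA / lambda_ij + theta_ijA)`
#' for every chemical species and
#' `d[X_i]/dt = X_i (sum_j r_ij / lambda_ij - k_d)` for every population.
#' Anabolic contributions are dropped for pathways whose rate is zero or
#' whose energy balance does not support growth.
#'
#' This is the reference (reaction-level) implementation; the simulator uses
#' a pre-compiled equivalent of the same arithmetic.
#'
#' @param populations List of [population()] objects.
#' @param species_set Species tibble.
#' @param concentrations Named vector of free species concentrations,
#'   mol L^-1.
#' @param biomass Named vector of biomass concentrations (names matching
#'   population names), C-mol L^-1.
#' @param pH Medium pH.
#' @param temperature Kelvin.
#' @param conc_floor Concentration floor for ln Q.
#' @param thermodynamics Force `F_T = 1` when `FALSE`.
#' @return List with `species` (named derivative vector over chemical
#'   species, mol L^-1 h^-1), `biomass` (named, C-mol L^-1 h^-1), and
#'   `pathway_states` (tibble of per-pathway diagnostics).
#' @export
community_derivatives <- function(populations, species_set, concentrations,
                                  biomass, pH, temperature,
                                  conc_floor = 1e-12, thermodynamics = TRUE) {
  rxn_species <- unique(unlist(lapply(populations, function(pop) {
    c(unlist(lapply(pop$pathways, function(pw) names(pw$rxn$coeffs))),
      names(pop$anabolic$rxn$coeffs))
  })))
  all_names <- union(names(concentrations), rxn_species)
  all_names <- setdiff(all_names, c("H+", "H2O"))
  dspec <- setNames(numeric(length(all_names)), all_names)
  dbio <- setNames(numeric(length(populations)),
                   vapply(populations, `[[`, "", "name"))
  states <- list()
  for (pop in populations) {
    x <- biomass[[pop$name]]
    growth <- 0
    for (pw in pop$pathways) {
      st <- pathway_specific_rate(pw, pop$anabolic, species_set,
                                  concentrations, pH, temperature,
                                  conc_floor, thermodynamics)
      st$population <- pop$name
      states[[length(states) + 1L]] <- st
      if (x <= 0 || st$rate <= 0) next
      for (nm in names(pw$rxn$coeffs)) {
        if (nm %in% c("H+", "H2O")) next
        dspec[nm] <- dspec[nm] + x * st$rate * pw$rxn$coeffs[[nm]]
      }
      if (!is.na(st$lambda)) {
        for (nm in names(pop$anabolic$rxn$coeffs)) {
          if (nm %in% c("H+", "H2O", pop$anabolic$biomass)) next
          dspec[nm] <- dspec[nm] +
            x * st$rate * pop$anabolic$rxn$coeffs[[nm]] / st$lambda
        }
        growth <- growth + st$rate / st$lambda
      }
    }
    dbio[pop$name] <- x * (growth - pop$k_d)
  }
  list(species = dspec, biomass = dbio,
       pathway_states = dplyr::bind_rows(states))
}
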