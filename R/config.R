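#' Assemble a simulation configuration
#'
#' Collects the chemistry (species, acid-base families, gas/liquid
#' exchanges), the biology (populations with their pathways), the vessel
#' geometry, the initial state, and solver settings into one validated
#' object. The aqueous state variables of a simulation are the *totals*
#' listed in `initial$totals` - one per acid-base family plus one per
#' non-speciating aqueous species - together with headspace contents
#' (`initial$gas`, mol per L of headspace) and per-population biomasses.
#'
#' @param species Species tibble (see [default_species()]).
#' @param families List of [acid_base_family()] objects.
#' @param exchanges List of [phase_exchange()] objects.
#' @param populations List of [population()] objects.
#' @param geometry A [phase_geometry()].
#' @param initial List with named numeric vectors `totals` (aqueous pools,
#'   mol L^-1) and `gas` (headspace pools, mol per L headspace), and either
#'   `biomass` (named per population, C-mol L^-1) or `od600` (a single
#'   optical density converted via [biomass_from_od()] and split evenly).
#' @param duration Simulated horizon, h.
#' @param output_times Optional explicit output grid, h.
#' @param solver List of solver settings; defaults
#'   `rtol = 1e-6`, `atol = 1e-12` (mol L^-1), `conc_floor = 1e-12`
#'   (mol L^-1, floor applied inside ln Q), `pKw = 14`, `ph_tol = 1e-12`.
#' @param od_calibration List with `slope` (5.12), `intercept` (4.987) of the
#'   log-linear dry-weight/OD600 relation and `biomass_molar_mass`
#'   (g C-mol^-1, default from the biomass formula).
#' @return An object of class `tc_config`.
#' @export
simulation_config <- function(species, families, exchanges, populations,
                              geometry, initial, duration = 504,
                              output_times = NULL, solver = list(),
                              od_calibration = list()) {
  stopifnot(duration >= 0, inherits(geometry, "tc_geometry"))
  solver <- utils::modifyList(
    list(rtol = 1e-6, atol = 1e-12, conc_floor = 1e-12, pKw = 14,
         ph_tol = 1e-12, maxsteps = 50000L),
    solver)
  od_calibration <- utils::modifyList(
    list(slope = 5.12, intercept = 4.987,
         biomass_molar_mass = molar_mass("C1H1.8O0.5N0.2")),
    od_calibration)
  families <- setNames(families, vapply(families, `[[`, "", "name"))
  populations <- setNames(populations, vapply(populations, `[[`, "", "name"))
  cfg <- structure(
    list(species = species, families = families, exchanges = exchanges,
         populations = populations, geometry = geometry, initial = initial,
         duration = duration, output_times = output_times, solver = solver,
         od_calibration = od_calibration),
    class = "tc_config")
  validate_config(cfg, quiet = TRUE)
  cfg
}

#' Validate a configuration
#'
#' Checks that every referenced name resolves, that reactions only involve
#' aqueous species, and surfaces element/charge imbalances of the declared
#' reactions as warnings.
#'
#' @param config A `tc_config`.
#' @param balance_tol Imbalance tolerance passed to [balance_check()].
#' @param quiet Suppress imbalance warnings.
#' @return The config, invisibly.
#' @export
validate_config <- function(config, balance_tol = 1e-3, quiet = FALSE) {
  sp <- config$species
  if (anyDuplicated(sp$name)) abort("duplicated species names")
  pool_names <- names(config$initial$totals)
  if (is.null(pool_names)) abort("initial$totals must be a named vector")
  if (any(config$initial$totals < -1e-15)) abort("initial totals must be >= 0")
  for (f in config$families) {
    if (!f$name %in% pool_names) {
      abort(sprintf("family '%s' has no entry in initial$totals", f$name))
    }
    for (m in f$members) {
      r <- species_row(sp, m)
      if (r$phase != "aqueous") {
        abort(sprintf("family member '%s' must be aqueous", m))
      }
    }
  }
  standalone <- setdiff(pool_names, names(config$families))
  for (nm in standalone) species_row(sp, nm)
  for (nm in names(config$initial$gas)) {
    if (species_row(sp, nm)$phase != "gas") {
      abort(sprintf("'%s' in initial$gas is not a gas species", nm))
    }
  }
  mapped <- c(unlist(lapply(config$families, `[[`, "members")), standalone)
  for (pop in config$populations) {
    rxns <- c(lapply(pop$pathways, function(p) p$rxn), list(pop$anabolic$rxn))
    for (rxn in rxns) {
      for (nm in names(rxn$coeffs)) {
        if (nm %in% c("H+", "H2O", pop$anabolic$biomass)) next
        r <- species_row(sp, nm)
        if (r$phase != "aqueous") {
          abort(sprintf(
            "reaction species '%s' is not aqueous; metabolic reactions act on dissolved species only", nm))
        }
        if (!nm %in% mapped) {
          abort(sprintf(
            "reaction species '%s' is not covered by any pool in initial$totals", nm))
        }
      }
      if (!quiet) {
        bal <- balance_check(rxn, sp, tol = balance_tol)
        bad <- bal[bal$flagged, ]
        if (nrow(bad)) {
          warn(sprintf("population '%s': reaction imbalance in %s (max |%.3g|)",
                       pop$name, paste(bad$quantity, collapse = ", "),
                       max(abs(bad$imbalance))))
        }
      }
    }
  }
  for (ex in config$exchanges) {
    if (species_row(sp, ex$aqueous)$phase != "aqueous" ||
        species_row(sp, ex$gas)$phase != "gas") {
      abort(sprintf("exchange %s/%s phases are wrong", ex$aqueous, ex$gas))
    }
    if (!ex$gas %in% names(config$initial$gas)) {
      abort(sprintf("gas species '%s' has no entry in initial$gas", ex$gas))
    }
    if (!ex$aqueous %in% mapped) {
      abort(sprintf("aqueous species '%s' of an exchange is not pooled", ex$aqueous))
    }
  }
  if (is.null(config$initial$biomass) && is.null(config$initial$od600)) {
    abort("initial must provide either biomass or od600")
  }
  invisible(config)
}

#' Look up or set the minimum-energy threshold of a pathway
#'
#' Calibration parameters are addressed as `"<population>:<pathway>"`.
#'
#' @param config A `tc_config`.
#' @param parameter Parameter label, e.g. `"Dv:lactate_fermentation"`.
#' @param value New `dG_min`, kJ mol^-1.
#' @return `set_dgmin()` returns the modified config; `get_dgmin()` the
#'   current value.
#' @export
set_dgmin <- function(config, parameter, value) {
  parts <- strsplit(parameter, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) abort("parameter label must be '<population>:<pathway>'")
  if (!parts[1] %in% names(config$populations) ||
      !parts[2] %in% names(config$populations[[parts[1]]]$pathways)) {
    abort(sprintf("unknown parameter '%s'", parameter))
  }
  config$populations[[parts[1]]]$pathways[[parts[2]]]$dG_min <- value
  config
}

#' @rdname set_dgmin
#' @export
get_dgmin <- function(config, parameter) {
  parts <- strsplit(parameter, ":", fixed = TRUE)[[1]]
  config$populations[[parts[1]]]$pathways[[parts[2]]]$dG_min
}

#' Write / read a configuration as YAML
#'
#' The YAML document has sections `species`, `families`, `exchanges`,
#' `populations`, `geometry`, `initial`, `duration` and `solver`, and
#' round-trips exactly through `read_config(write_config(x))`.
#'
#' @param config A `tc_config`.
#' @param path File path.
#' @return `write_config()` the path invisibly; `read_config()` a
#'   `tc_config`.
#' @export
write_config <- function(config, path) {
  doc <- list(
    species = lapply(seq_len(nrow(config$species)), function(i) {
      r <- config$species[i, ]
      comp <- r$composition[[1]]
      list(name = r$name, phase = r$phase,
           composition = paste0(names(comp), comp, collapse = ""),
           charge = r$charge, dGf0 = r$dGf0,
           dHf0 = if (is.na(r$dHf0)) NULL else r$dHf0)
    }),
    families = lapply(unname(config$families), function(f) {
      list(name = f$name, members = as.list(f$members), pK = as.list(f$pK))
    }),
    exchanges = lapply(unname(config$exchanges), function(e) {
      list(aqueous = e$aqueous, gas = e$gas, kLa = e$kLa, H_ref = e$H_ref,
           dH_sol_K = e$dH_sol_K)
    }),
    populations = lapply(unname(config$populations), function(p) {
      list(name = p$name, k_d = p$k_d,
           anabolic = list(coeffs = as.list(p$anabolic$rxn$coeffs),
                           donor = p$anabolic$donor,
                           biomass = p$anabolic$biomass),
           pathways = lapply(unname(p$pathways), function(pw) {
             list(name = pw$name, coeffs = as.list(pw$rxn$coeffs),
                  reference = pw$rxn$reference, v_max = pw$v_max,
                  K_S = as.list(pw$K_S), dG_min = pw$dG_min,
                  dG_met = pw$dG_met)
           }))
    }),
    geometry = list(V_aq = config$geometry$V_aq, V_g = config$geometry$V_g,
                    temperature = config$geometry$temperature),
    initial = list(totals = as.list(config$initial$totals),
                   gas = as.list(config$initial$gas),
                   biomass = if (!is.null(config$initial$biomass)) {
                     as.list(config$initial$biomass)
                   } else NULL,
                   od600 = config$initial$od600),
    duration = config$duration,
    solver = config$solver,
    od_calibration = config$od_calibration
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  num <- function(x) setNames(vapply(x, as.numeric, 0), names(x))
  species <- tibble::tibble(
    name = vapply(doc$species, `[[`, "", "name"),
    phase = vapply(doc$species, `[[`, "", "phase"),
    composition = lapply(doc$species, function(s) parse_composition(s$composition)),
    charge = vapply(doc$species, function(s) as.numeric(s$charge), 0),
    dGf0 = vapply(doc$species, function(s) as.numeric(s$dGf0), 0),
    dHf0 = vapply(doc$species, function(s) {
      if (is.null(s$dHf0)) NA_real_ else as.numeric(s$dHf0)
    }, 0)
  )
  families <- lapply(doc$families, function(f) {
    acid_base_family(f$name, unlist(f$members), unlist(f$pK))
  })
  exchanges <- lapply(doc$exchanges, function(e) {
    phase_exchange(e$aqueous, e$gas, e$kLa, e$H_ref, e$dH_sol_K)
  })
  populations <- lapply(doc$populations, function(p) {
    ana <- anabolic_reaction(reaction(num(p$anabolic$coeffs)),
                             donor = p$anabolic$donor,
                             biomass = p$anabolic$biomass)
    pws <- lapply(p$pathways, function(pw) {
      catabolic_pathway(pw$name, reaction(num(pw$coeffs), pw$reference),
                        v_max = pw$v_max, K_S = num(pw$K_S),
                        dG_min = pw$dG_min, dG_met = pw$dG_met)
    })
    population(p$name, pws, ana, k_d = p$k_d)
  })
  simulation_config(
    species = species, families = families, exchanges = exchanges,
    populations = populations,
    geometry = phase_geometry(doc$geometry$V_aq, doc$geometry$V_g,
                              doc$geometry$temperature),
    initial = list(totals = num(doc$initial$totals),
                   gas = num(doc$initial$gas),
                   biomass = if (!is.null(doc$initial$biomass)) {
                     num(doc$initial$biomass)
                   },
                   od600 = doc$initial$od600),
    duration = doc$duration, solver = doc$solver,
    od_calibration = doc$od_calibration)
}
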