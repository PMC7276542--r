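#' Standard-condition energetics of every declared pathway
#'
#' Evaluates the Gibbs energy of each catabolic pathway and each anabolic
#' reaction of a configuration at reference conditions: a chosen pH, unit
#' activity for every other species, and the system temperature. This is the
#' conventional way pathway energetics are tabulated for anaerobic
#' communities.
#'
#' @param config A `tc_config`.
#' @param pH Reference pH (default 7).
#' @param temperature Kelvin (default: the configured system temperature).
#' @return Tibble with columns `population`, `reaction` (pathway name or
#'   `"anabolism"`), `reference` (the normalizing substrate, `NA` for
#'   anabolism), `dG` (kJ per mol of reference substrate, or per C-mol
#'   biomass for anabolism) and `dG_per_mol` of each consumed co-substrate
#'   is obtainable by rescaling with the stoichiometry.
#' @export
pathway_energetics <- function(config, pH = 7, temperature = NULL) {
  temperature <- temperature %||% config$geometry$temperature
  rows <- lapply(config$populations, function(pop) {
    pw <- lapply(pop$pathways, function(p) {
      tibble::tibble(population = pop$name, reaction = p$name,
                     reference = p$rxn$reference,
                     dG = reaction_energy(p$rxn, config$species,
                                          pH = pH, temperature = temperature))
    })
    ana <- tibble::tibble(
      population = pop$name, reaction = "anabolism", reference = NA_character_,
      dG = reaction_energy(pop$anabolic$rxn, config$species,
                           pH = pH, temperature = temperature))
    dplyr::bind_rows(c(pw, list(ana)))
  })
  dplyr::bind_rows(rows)
}
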