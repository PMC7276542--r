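#' Declare a chemical species
#'
#' A species is a named chemical identity in one phase. Aqueous and gas twins
#' of the same substance (e.g. `H2(aq)` and `H2(g)`) are distinct species.
#'
#' @param name Unique species name.
#' @param phase `"aqueous"` or `"gas"`.
#' @param composition Elemental composition (string or named count vector).
#' @param charge Formal charge (may be fractional), dimensionless.
#' @param dGf0 Standard Gibbs energy of formation at 298.15 K, kJ mol^-1.
#' @param dHf0 Standard enthalpy of formation at 298.15 K, kJ mol^-1, or `NA`
#'   if unavailable (formation energy is then used without temperature
#'   adjustment).
#' @return An object of class `tc_species`.
#' @export
chem_species <- function(name, phase = c("aqueous", "gas"), composition,
                         charge = 0, dGf0 = NA_real_, dHf0 = NA_real_) {
  phase <- match.arg(phase)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(
    list(name = name, phase = phase,
         composition = parse_composition(composition),
         charge = as.numeric(charge), dGf0 = as.numeric(dGf0),
         dHf0 = as.numeric(dHf0)),
    class = "tc_species"
  )
}

#' @export
print.tc_species <- function(x, ...) {
  comp <- paste0(names(x$composition),
                 ifelse(x$composition == 1, "", x$composition), collapse = "")
  cat(sprintf("<species> %s [%s] %s charge %+g dGf0 %s kJ/mol\n",
              x$name, x$phase, comp, x$charge,
              ifelse(is.na(x$dGf0), "?", format(x$dGf0))))
  invisible(x)
}

#' Species set bundled with the package
#'
#' Reads the shipped formation-energy table (a curated compilation in the
#' Thauer/Alberty lineage, with enthalpies of formation where available) into
#' a tibble of species. Users can append or override rows before building a
#' configuration.
#'
#' @param path Optional path to an alternative delimited table with columns
#'   `name`, `phase`, `composition`, `charge`, `dGf0`, `dHf0`.
#' @return Tibble with one row per species; `composition` is a list-column of
#'   named count vectors.
#' @export
default_species <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "formation_energies.tsv",
                        package = "thermocomm", mustWork = TRUE)
  }
  raw <- read.delim(path, stringsAsFactors = FALSE)
  tibble::tibble(
    name = raw$name,
    phase = raw$phase,
    composition = lapply(raw$composition, parse_composition),
    charge = as.numeric(raw$charge),
    dGf0 = as.numeric(raw$dGf0),
    dHf0 = as.numeric(raw$dHf0)
  )
}

species_row <- function(species_set, name) {
  i <- match(name, species_set$name)
  if (is.na(i)) abort(sprintf("unknown species '%s'", name))
  species_set[i, ]
}

#' Define a reaction
#'
#' Reactions are signed stoichiometric maps over species names (reactants
#' negative, products positive; fractional coefficients allowed), normalized
#' to a reference substrate carried with coefficient -1.
#'
#' @param coeffs Named numeric vector of stoichiometric coefficients.
#' @param reference Name of the reference substrate (coefficient must be -1).
#'   Optional for reactions that are not pathway-normalized (e.g. anabolic
#'   reactions normalized to +1 biomass instead).
#' @return An object of class `tc_reaction`.
#' @examples
#' reaction(c("lactate" = -1, "H2O" = -2, "acetate" = 1,
#'            "H2(aq)" = 2, "HCO3" = 1, "H+" = 1), reference = "lactate")
#' @export
reaction <- function(coeffs, reference = NULL) {
  stopifnot(is.numeric(coeffs), length(coeffs) > 0L, !is.null(names(coeffs)))
  if (anyDuplicated(names(coeffs))) abort("duplicated species in reaction")
  if (!is.null(reference)) {
    if (!reference %in% names(coeffs) || coeffs[[reference]] != -1) {
      abort(sprintf(
        "reference species '%s' must be present with coefficient -1", reference))
    }
  }
  structure(list(coeffs = coeffs, reference = reference), class = "tc_reaction")
}

#' @export
print.tc_reaction <- function(x, ...) {
  lhs <- x$coeffs[x$coeffs < 0]
  rhs <- x$coeffs[x$coeffs > 0]
  side <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                   paste0(abs(v), " ", names(v))), collapse = " + ")
  cat("<reaction>", side(lhs), "->", side(rhs), "\n")
  invisible(x)
}

#' Element and charge balance of a reaction
#'
#' Reports the net amount of every element and of charge created by the
#' reaction as written. Printed stoichiometries in the literature often carry
#' rounding, so imbalances are reported rather than rejected.
#'
#' @param rxn A [reaction()].
#' @param species_set Species tibble (see [default_species()]).
#' @param tol Absolute imbalance above which an entry is flagged.
#' @return Tibble with columns `quantity` (element symbol or `"charge"`),
#'   `imbalance`, and `flagged`.
#' @export
balance_check <- function(rxn, species_set, tol = 1e-6) {
  stopifnot(inherits(rxn, "tc_reaction"))
  rows <- lapply(names(rxn$coeffs), function(nm) species_row(species_set, nm))
  elements <- sort(unique(unlist(lapply(rows, function(r) names(r$composition[[1]])))))
  bal <- setNames(numeric(length(elements) + 1L), c(elements, "charge"))
  for (k in seq_along(rows)) {
    v <- rxn$coeffs[[k]]
    comp <- rows[[k]]$composition[[1]]
    bal[names(comp)] <- bal[names(comp)] + v * comp
    bal["charge"] <- bal["charge"] + v * rows[[k]]$charge
  }
  tibble::tibble(
    quantity = names(bal),
    imbalance = as.numeric(bal),
    flagged = abs(as.numeric(bal)) > tol
  )
}
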