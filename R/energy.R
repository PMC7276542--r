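#' Gibbs energy of formation adjusted to temperature
#'
#' Applies the linear Gibbs-Helmholtz form
#' `dGf(T) = dHf - (T / 298.15) * (dHf - dGf0)` when an enthalpy of formation
#' is available; otherwise returns the 298.15 K value unchanged.
#'
#' @param dGf0,dHf0 Formation energy and enthalpy at 298.15 K, kJ mol^-1.
#' @param temperature Kelvin.
#' @return Formation energy at `temperature`, kJ mol^-1.
#' @export
formation_energy_at <- function(dGf0, dHf0, temperature) {
  out <- dGf0
  ok <- !is.na(dHf0)
  out[ok] <- dHf0[ok] - (temperature / .TREF) * (dHf0[ok] - dGf0[ok])
  out
}

# Effective formation energies (kJ/mol) for every species of a reaction,
# with the proton fixed at 0 by convention.
.reaction_g <- function(rxn, species_set, temperature) {
  vapply(names(rxn$coeffs), function(nm) {
    if (nm == "H+") return(0)
    r <- species_row(species_set, nm)
    if (is.na(r$dGf0)) {
      abort(sprintf("species '%s' has no formation energy", nm))
    }
    formation_energy_at(r$dGf0, r$dHf0, temperature)
  }, numeric(1))
}

#' Standard-state reaction Gibbs energy
#'
#' Sum of stoichiometry-weighted formation energies at the given temperature
#' (all activities 1, including the proton). Units follow the reaction
#' normalization: kJ per mol of the reference substrate.
#'
#' @param rxn A [reaction()].
#' @param species_set Species tibble with formation energies.
#' @param temperature Kelvin.
#' @return Numeric scalar, kJ mol^-1.
#' @export
standard_reaction_energy <- function(rxn, species_set, temperature = .TREF) {
  g <- .reaction_g(rxn, species_set, temperature)
  sum(rxn$coeffs * g)
}

#' Reaction Gibbs energy at given activities, pH and temperature
#'
#' `dG = dG0(T) + R T ln Q`, with `Q` the mass-action ratio over all species
#' carrying a nonzero coefficient. By convention the proton activity is
#' `10^-pH`, the water activity is 1, and both are taken from those
#' conventions rather than from `activities`. Concentrations are used as
#' activities (no ionic-strength correction).
#'
#' @param rxn A [reaction()].
#' @param species_set Species tibble with formation energies.
#' @param activities Named numeric vector of activities (mol L^-1 for
#'   dissolved species) covering every participating species other than
#'   `H+` and `H2O`. Species missing from the vector default to activity 1.
#' @param pH Medium pH.
#' @param temperature Kelvin.
#' @return Numeric scalar, kJ per mol of reference substrate.
#' @export
reaction_energy <- function(rxn, species_set, activities = numeric(),
                            pH = 7, temperature = .TREF) {
  dg0 <- standard_reaction_energy(rxn, species_set, temperature)
  rt <- .RGAS * temperature
  lnq <- 0
  for (nm in names(rxn$coeffs)) {
    v <- rxn$coeffs[[nm]]
    a <- if (nm == "H+") {
      10^(-pH)
    } else if (nm == "H2O") {
      1
    } else if (nm %in% names(activities)) {
      activities[[nm]]
    } else {
      1
    }
    if (a <= 0 || !is.finite(a)) {
      abort(sprintf(
        "non-positive activity for species '%s'; apply a concentration floor first", nm))
    }
    lnq <- lnq + v * log(a)
  }
  dg0 + rt * lnq
}
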