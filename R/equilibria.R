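#' Declare an acid-base family
#'
#' An ordered ladder of conjugate aqueous species, most protonated first,
#' with one pK per deprotonation step. The simulator carries one state
#' variable per family (the total concentration); free member concentrations
#' follow from the pH.
#'
#' @param name Family name (also the name of its total pool).
#' @param members Character vector of member species names, most protonated
#'   first.
#' @param pK Numeric vector of pK values, strictly increasing, one fewer than
#'   members.
#' @return An object of class `tc_family`.
#' @examples
#' acid_base_family("acetate", c("acetic_acid", "acetate"), pK = 4.76)
#' @export
acid_base_family <- function(name, members, pK) {
  stopifnot(length(members) >= 2L, length(pK) == length(members) - 1L)
  if (length(pK) > 1L && any(diff(pK) <= 0)) {
    abort(sprintf("pK values of family '%s' must be strictly increasing", name))
  }
  structure(list(name = name, members = members, pK = as.numeric(pK)),
            class = "tc_family")
}

#' Ionization fractions of an acid-base family at a given pH
#'
#' Closed-form speciation ladder: the fraction of the k-th member (0-indexed
#' deprotonation depth) is proportional to `10^(k pH - sum(pK[1..k]))`.
#'
#' @param family A [acid_base_family()].
#' @param pH Medium pH.
#' @return Named numeric vector of fractions (non-negative, summing to 1).
#' @export
speciation_fractions <- function(family, pH) {
  stopifnot(is.finite(pH))
  expo <- c(0, cumsum(pH - family$pK))
  expo <- expo - max(expo) # overflow guard
  w <- 10^expo
  setNames(w / sum(w), family$members)
}

#' Solution inventory for charge-balance pH determination
#'
#' @param families List of [acid_base_family()] objects.
#' @param totals Named numeric vector of family total concentrations,
#'   mol L^-1 (names matching family names).
#' @param free_ions Named numeric vector of concentrations of non-speciating
#'   charged (or neutral) species, mol L^-1.
#' @param species_set Species tibble supplying member charges.
#' @param pKw Water autoionization pK (default 14, the 25 degree C value).
#' @return An object of class `tc_totals`.
#' @export
solution_totals <- function(families = list(), totals = numeric(),
                            free_ions = numeric(),
                            species_set = default_species(), pKw = 14) {
  families <- stats::setNames(families, vapply(families, `[[`, "", "name"))
  missing <- setdiff(names(families), names(totals))
  if (length(missing)) {
    abort(sprintf("no total concentration for family/ies: %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(totals < 0) || (length(free_ions) && any(free_ions < 0))) {
    abort("concentrations must be non-negative")
  }
  charge_of <- function(nm) species_row(species_set, nm)$charge
  member_charges <- lapply(families, function(f) vapply(f$members, charge_of, 0))
  ion_charges <- if (length(free_ions)) {
    vapply(names(free_ions), charge_of, 0)
  } else numeric()
  structure(list(families = families, totals = totals, free_ions = free_ions,
                 member_charges = member_charges, ion_charges = ion_charges,
                 pKw = pKw),
            class = "tc_totals")
}

#' Net charge of the solution at a trial pH
#'
#' Sums `charge * concentration` over every speciated family member (via
#' [speciation_fractions()]), every fixed ion, plus `[H+] - [OH-]`.
#'
#' @param totals A [solution_totals()] inventory.
#' @param pH Trial pH.
#' @return Net charge, eq L^-1 (monotonically decreasing in pH).
#' @export
charge_imbalance <- function(totals, pH) {
  z <- 10^(-pH) - 10^(pH - totals$pKw)
  for (nm in names(totals$families)) {
    fr <- speciation_fractions(totals$families[[nm]], pH)
    z <- z + totals$totals[[nm]] * sum(fr * totals$member_charges[[nm]])
  }
  if (length(totals$free_ions)) {
    z <- z + sum(totals$free_ions * totals$ion_charges)
  }
  z
}

#' Solve the medium pH from the charge balance
#'
#' Brent-type bracketed root finding (via [stats::uniroot()]) of
#' [charge_imbalance()] on pH in `[0, 14]`. The convergence criterion is on
#' the charge residual, not on pH.
#'
#' @param totals A [solution_totals()] inventory.
#' @param tol Residual tolerance, eq L^-1.
#' @return The pH at which the solution is electroneutral.
#' @export
solve_ph <- function(totals, tol = 1e-12) {
  f <- function(p) charge_imbalance(totals, p)
  lo <- f(0); hi <- f(14)
  if (sign(lo) == sign(hi)) {
    abort(sprintf(
      "charge balance has no root in pH [0, 14] (residuals %.3e and %.3e); the ion inventory is unphysical",
      lo, hi))
  }
  r <- uniroot(f, c(0, 14), f.lower = lo, f.upper = hi, tol = 1e-13)
  # polish to the residual tolerance by bisection if needed
  p <- r$root
  if (abs(f(p)) > tol) {
    a <- max(0, p - 1e-3); b <- min(14, p + 1e-3)
    fa <- f(a); fb <- f(b)
    if (sign(fa) != sign(fb)) {
      for (i in 1:200) {
        m <- (a + b) / 2; fm <- f(m)
        if (abs(fm) <= tol) break
        if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else { b <- m; fb <- fm }
      }
      p <- (a + b) / 2
    }
  }
  p
}
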