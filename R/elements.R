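# Standard atomic weights (IUPAC 2021 abridged), g mol^-1.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Na = 22.990, K = 39.098, Cl = 35.45, Ca = 40.078, Mg = 24.305, Fe = 55.845
)

#' Parse an elemental composition string
#'
#' Converts a Hill-style formula such as `"C1H1.8O0.5N0.2"` or `"H2O"` into a
#' named numeric vector of element counts. Counts may be fractional, as is
#' conventional for carbon-mole biomass formulas.
#'
#' @param x A formula string, or an already-parsed named numeric vector
#'   (returned unchanged after validation).
#' @return Named numeric vector of element counts.
#' @examples
#' parse_composition("C1H1.8O0.5N0.2")
#' parse_composition("H2O")
#' @export
parse_composition <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else {
    stopifnot(is.character(x), length(x) == 1L, nzchar(x))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x, perl = TRUE)[[1]]
    toks <- regmatches(x, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(x)) {
      abort(sprintf("cannot parse composition string '%s'", x))
    }
    el <- sub("[0-9.]*$", "", toks)
    ct <- sub("^[A-Za-z]+", "", toks)
    counts <- ifelse(ct == "", 1, suppressWarnings(as.numeric(ct)))
    names(counts) <- el
    counts <- tapply(counts, names(counts), sum)
    counts <- setNames(as.numeric(counts), names(counts))
  }
  if (length(counts) == 0L || all(counts == 0)) {
    abort("composition must contain at least one element with a positive count")
  }
  if (any(counts < 0) || anyNA(counts)) {
    abort("element counts must be non-negative numbers")
  }
  counts
}

#' Molar mass of an elemental composition
#'
#' @param composition Formula string, named count vector, or [chem_species()]
#'   object.
#' @return Mass per formula unit, g mol^-1 (g C-mol^-1 for carbon-mole
#'   biomass formulas).
#' @examples
#' molar_mass("C1H1.8O0.5N0.2") # 24.6 g C-mol^-1
#' molar_mass("H2O")
#' @export
molar_mass <- function(composition) {
  if (inherits(composition, "tc_species")) composition <- composition$composition
  counts <- parse_composition(composition)
  unknown <- setdiff(names(counts), names(.ATOMIC_WEIGHTS))
  if (length(unknown)) {
    abort(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")))
  }
  sum(counts * .ATOMIC_WEIGHTS[names(counts)])
}
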