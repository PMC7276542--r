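#' Declare a gas/liquid exchange pair
#'
#' Links an aqueous species to its gas-phase twin through two-film transfer
#' with a volumetric mass-transfer coefficient `k_La` and a Henry solubility
#' constant.
#'
#' @param aqueous,gas Names of the dissolved and headspace species.
#' @param kLa Volumetric mass-transfer coefficient, h^-1 (>= 0).
#' @param H_ref Henry solubility at 298.15 K, mol m^-3 Pa^-1 (> 0).
#' @param dH_sol_K Temperature-dependence coefficient `-dH_sol/R`, K. With
#'   the standard positive convention solubility decreases as temperature
#'   rises above 298.15 K.
#' @return An object of class `tc_exchange`.
#' @export
phase_exchange <- function(aqueous, gas, kLa, H_ref, dH_sol_K = 0) {
  stopifnot(kLa >= 0, H_ref > 0)
  structure(list(aqueous = aqueous, gas = gas, kLa = kLa,
                 H_ref = H_ref, dH_sol_K = dH_sol_K),
            class = "tc_exchange")
}

#' Culture vessel geometry
#'
#' @param V_aq Liquid volume, L.
#' @param V_g Headspace volume, L.
#' @param temperature Kelvin.
#' @return An object of class `tc_geometry`.
#' @export
phase_geometry <- function(V_aq, V_g, temperature = 310.15) {
  stopifnot(V_aq > 0, V_g > 0, temperature > 0)
  structure(list(V_aq = V_aq, V_g = V_g, temperature = temperature),
            class = "tc_geometry")
}

#' Henry solubility adjusted to temperature
#'
#' Van 't Hoff form `H(T) = H_ref * exp(c * (1/T - 1/298.15))` with `c` the
#' tabulated temperature coefficient in K.
#'
#' @param spec A [phase_exchange()].
#' @param temperature Kelvin.
#' @return Henry solubility at `temperature`, mol m^-3 Pa^-1.
#' @export
henry_at_temperature <- function(spec, temperature) {
  stopifnot(temperature > 0)
  spec$H_ref * exp(spec$dH_sol_K * (1 / temperature - 1 / .TREF))
}

# Equilibrium aqueous concentration (mol/L) corresponding to a headspace
# content in mol per L of headspace: p = C_g * 1000 * R_J * T  (Pa), then
# C_eq = H(T) * p / 1000.  The two factors of 1000 cancel.
henry_equilibrium_conc <- function(gas_conc, spec, temperature) {
  henry_at_temperature(spec, temperature) * .RGAS_J * temperature * gas_conc
}

#' Two-film gas/liquid transfer derivatives
#'
#' `d[aq]/dt = -k_La ([aq] - C_eq)` and
#' `d[gas]/dt = +k_La (V_aq/V_g) ([aq] - C_eq)`, where `C_eq` is the
#' Henry-equilibrium aqueous concentration for the current headspace content.
#' Both concentrations are per litre of their own phase, so total moles
#' `V_aq [aq] + V_g [gas]` are conserved exactly.
#'
#' @param aq_conc Dissolved concentration, mol L^-1.
#' @param gas_conc Headspace content, mol per L of headspace.
#' @param spec A [phase_exchange()].
#' @param geom A [phase_geometry()].
#' @return Named numeric vector `c(aq = ..., gas = ...)`, mol L^-1 h^-1.
#' @export
transfer_derivatives <- function(aq_conc, gas_conc, spec, geom) {
  stopifnot(aq_conc >= 0, gas_conc >= 0)
  drive <- aq_conc - henry_equilibrium_conc(gas_conc, spec, geom$temperature)
  c(aq = -spec$kLa * drive, gas = spec$kLa * (geom$V_aq / geom$V_g) * drive)
}

# transfer-only two-state integration, used by fit_kla and the
# gas-equilibration fixture
integrate_transfer <- function(times, aq0, gas0, spec, geom) {
  deriv <- function(t, y, parms) {
    d <- transfer_derivatives(max(y[1], 0), max(y[2], 0), spec, geom)
    list(c(d[["aq"]], d[["gas"]]))
  }
  out <- deSolve::ode(c(aq = aq0, gas = gas0), times, deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-14)
  tibble::tibble(time = out[, "time"], aq = out[, "aq"], gas = out[, "gas"])
}

#' Estimate k_La from a gas equilibration time series
#'
#' Fits the volumetric mass-transfer coefficient by minimizing the sum of
#' squared error between the observed headspace time series and the
#' integrated two-film transfer dynamics, using bounded scalar minimization
#' over `[1e-4, 1e3]` h^-1 (searched on a log10 scale).
#'
#' @param observed Data frame with columns `time` (h) and `value` (headspace
#'   concentration, mol per L of headspace); at least 3 time points.
#' @param spec A [phase_exchange()]; its `kLa` entry is ignored.
#' @param geom A [phase_geometry()].
#' @param initial Named vector `c(aq = ..., gas = ...)` giving the state at
#'   time 0.
#' @return Fitted `k_La`, h^-1.
#' @export
fit_kla <- function(observed, spec, geom, initial) {
  stopifnot(nrow(observed) >= 3L, all(c("time", "value") %in% names(observed)))
  ceq0 <- henry_equilibrium_conc(initial[["gas"]], spec, geom$temperature)
  drive0 <- abs(initial[["aq"]] - ceq0)
  scale0 <- max(abs(initial[["aq"]]), abs(ceq0), 1e-30)
  if (drive0 / scale0 < 1e-6) {
    abort("system starts at Henry equilibrium; k_La is unidentifiable")
  }
  times <- sort(unique(c(0, observed$time)))
  sse <- function(log10k) {
    sp <- spec; sp$kLa <- 10^log10k
    sim <- integrate_transfer(times, initial[["aq"]], initial[["gas"]], sp, geom)
    pred <- approx(sim$time, sim$gas, xout = observed$time)$y
    sum((pred - observed$value)^2)
  }
  opt <- optimize(sse, c(-4, 3), tol = 1e-9)
  10^opt$minimum
}
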