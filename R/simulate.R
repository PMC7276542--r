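#' Initial biomass from optical density
#'
#' Converts OD600 to dry weight via the log-linear calibration
#' `ln(DW) = slope * OD600 - intercept` (DW in g L^-1), then to C-mol L^-1
#' with the biomass molar mass, and splits the total evenly between the
#' populations of the configuration.
#'
#' @param od600 Optical density at 600 nm (> 0).
#' @param config A `tc_config` (supplies the calibration constants and the
#'   population list).
#' @return Named vector of per-population biomass, C-mol L^-1; the total is
#'   `sum()` of it.
#' @export
biomass_from_od <- function(od600, config) {
  if (!is.numeric(od600) || length(od600) != 1L || od600 <= 0) {
    abort("od600 must be a single positive number")
  }
  cal <- config$od_calibration
  dw <- exp(cal$slope * od600 - cal$intercept)
  total <- dw / cal$biomass_molar_mass
  n <- length(config$populations)
  setNames(rep(total / n, n), names(config$populations))
}

#' Time derivative of the full system state
#'
#' Executes the per-step procedure of the simulator: (i) solve the pH from
#' the charge balance and speciate every pool, (ii) evaluate the biochemical
#' (growth) and gas/liquid transfer derivative terms separately,
#' (iii) return their sum. `terms` restricts the output to one of the two
#' halves, which is how the decomposition is tested.
#'
#' @param config A `tc_config`.
#' @param state Named state vector (defaults to the configured initial
#'   state): aqueous pool totals, headspace contents, biomasses.
#' @param terms `"all"`, `"biochemistry"` or `"transfer"`.
#' @param thermodynamics Force `F_T = 1` in every pathway when `FALSE`.
#' @return Named derivative vector (per hour) with attribute `pH`.
#' @export
state_derivative <- function(config, state = NULL,
                             terms = c("all", "biochemistry", "transfer"),
                             thermodynamics = TRUE) {
  terms <- match.arg(terms)
  sys <- compile_system(config, thermodynamics = thermodynamics)
  if (is.null(state)) state <- initial_state(config, sys)
  out <- sys$derivative(state[sys$pools], terms = terms)
  structure(setNames(out$d, sys$pools), pH = out$pH)
}

#' Simulate a community
#'
#' Integrates the coupled chemistry/biology system with an adaptive
#' stiff-capable solver ([deSolve::lsoda()]). The medium pH is re-solved
#' algebraically (charge balance, Brent bracketing) inside every derivative
#' evaluation; it is a diagnostic, not a state variable.
#'
#' @param config A `tc_config`.
#' @param thermodynamics With `FALSE`, the thermodynamic factor is forced to
#'   1 in every pathway (pure forward-kinetics variant); the energy-balance
#'   coupling then engages whenever the catabolic energy is negative.
#' @param output_times Optional output grid, h (default: hourly over the
#'   configured duration).
#' @return A `tc_trajectory`: tidy access via [as_tibble()] /
#'   [trajectory_wide()], plotting via [autoplot()].
#' @export
simulate_community <- function(config, thermodynamics = TRUE,
                               output_times = NULL) {
  sys <- compile_system(config, thermodynamics = thermodynamics)
  y0 <- initial_state(config, sys)
  times <- output_times %||% config$output_times %||%
    seq(0, config$duration, by = max(min(1, config$duration), 1e-9))
  if (config$duration == 0 || length(times) == 1L) {
    wide <- finish_trajectory(matrix(y0, nrow = 1,
                                     dimnames = list(NULL, sys$pools)),
                              0, sys)
    return(new_trajectory(wide, config, thermodynamics))
  }
  rhs <- function(t, y, parms) list(sys$derivative(y)$d)
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = config$solver$rtol, atol = config$solver$atol,
                        maxsteps = config$solver$maxsteps)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    last <- sol[nrow(sol), ]
    abort(sprintf("integration failed at t = %.3f h; last state: %s",
                  last[["time"]],
                  paste(sprintf("%s=%.3g", sys$pools,
                                last[-1][seq_along(sys$pools)]),
                        collapse = ", ")))
  }
  wide <- finish_trajectory(sol[, sys$pools, drop = FALSE], sol[, "time"], sys)
  new_trajectory(wide, config, thermodynamics)
}

# append pH and total biomass columns; clip solver undershoot at 0
finish_trajectory <- function(states, times, sys) {
  states <- pmax(states, 0)
  ph <- vapply(seq_len(nrow(states)), function(i) {
    sys$solve_ph(states[i, seq_len(sys$n_aq)])
  }, 0)
  bio_tot <- if (sys$n_bio > 1) {
    rowSums(states[, sys$bio_pools, drop = FALSE])
  } else {
    states[, sys$bio_pools]
  }
  tibble::as_tibble(as.data.frame(states)) |>
    dplyr::mutate(time = as.numeric(times), pH = ph,
                  biomass_total = as.numeric(bio_tot), .before = 1)
}
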