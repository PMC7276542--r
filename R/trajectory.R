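new_trajectory <- function(wide, config, thermodynamics) {
  structure(list(wide = wide, config = config,
                 thermodynamics = thermodynamics),
            class = "tc_trajectory")
}

#' @export
print.tc_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over %.6g h, %d variables (%s)\n",
              nrow(x$wide), max(x$wide$time), ncol(x$wide) - 1L,
              if (x$thermodynamics) "thermodynamic" else "forward-kinetics"))
  print(utils::head(x$wide, 4))
  invisible(x)
}

#' Wide-format trajectory table
#'
#' One row per output time; columns `time`, `pH`, `biomass_total`, every
#' aqueous pool total (mol L^-1), every headspace pool (mol per L headspace)
#' and every population biomass (`X_<name>`, C-mol L^-1).
#'
#' @param traj A `tc_trajectory`.
#' @return A tibble.
#' @export
trajectory_wide <- function(traj) traj$wide

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy (long) trajectory
#'
#' @param x A `tc_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `variable`, `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.tc_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$wide, -"time", names_to = "variable",
                      values_to = "value")
}

# linear interpolation of one trajectory variable at arbitrary times
trajectory_at <- function(traj, variable, times) {
  if (!variable %in% names(traj$wide)) {
    abort(sprintf("variable '%s' is not among the model outputs", variable))
  }
  approx(traj$wide$time, traj$wide[[variable]], xout = times, rule = 2)$y
}

#' Per-pathway diagnostics along a trajectory
#'
#' Re-evaluates every pathway (energies, kinetic and thermodynamic factors,
#' specific rate, dynamic stoichiometry and yield) at each output time.
#'
#' @param traj A `tc_trajectory`.
#' @return Tibble with one row per time x population x pathway.
#' @export
trajectory_diagnostics <- function(traj) {
  cfg <- traj$config
  sys <- compile_system(cfg, thermodynamics = traj$thermodynamics)
  wide <- traj$wide
  rows <- lapply(seq_len(nrow(wide)), function(i) {
    totals <- unlist(wide[i, sys$aq_pools], use.names = FALSE)
    ph <- wide$pH[i]
    free <- setNames(sys$speciate(totals, ph), sys$free_names)
    out <- lapply(cfg$populations, function(pop) {
      dplyr::bind_rows(lapply(pop$pathways, function(pw) {
        pathway_specific_rate(pw, pop$anabolic, cfg$species, free, ph,
                              cfg$geometry$temperature,
                              cfg$solver$conc_floor,
                              thermodynamics = traj$thermodynamics)
      })) |>
        dplyr::mutate(population = pop$name, .before = 1)
    })
    dplyr::bind_rows(out) |> dplyr::mutate(time = wide$time[i], .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Plot a trajectory
#'
#' Faceted time courses of a chosen set of variables.
#'
#' @param object A `tc_trajectory`.
#' @param variables Character vector of variable names (default: every
#'   non-fixed variable).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tc_trajectory <- function(object, variables = NULL, ...) {
  long <- as_tibble(object)
  if (is.null(variables)) {
    keep <- long |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(span = diff(range(.data$value))) |>
      dplyr::filter(.data$span > 0)
    variables <- keep$variable
  }
  long <- dplyr::filter(long, .data$variable %in% variables)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL)
}
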