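#' Tidy a calibration fit
#'
#' @param x A `tc_fit` from [hierarchical_calibrate()].
#' @param ... Unused.
#' @return Tibble with one row per calibrated parameter: `parameter`,
#'   `estimate` (kJ mol^-1) and `identifiable`.
#' @exportS3Method generics::tidy
tidy.tc_fit <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$parameters),
    estimate = unname(x$parameters),
    identifiable = !names(x$parameters) %in% x$unidentifiable
  )
}

#' One-line summary of a calibration fit
#'
#' @param x A `tc_fit`.
#' @param ... Unused.
#' @return One-row tibble: final weighted error, parameter and observation
#'   counts, number of optimizer passes, seed.
#' @exportS3Method generics::glance
glance.tc_fit <- function(x, ...) {
  tibble::tibble(
    error = x$error,
    n_parameters = length(x$parameters),
    n_observations = nrow(x$observations),
    n_passes = if (nrow(x$trace)) max(x$trace$pass) else 0L,
    seed = x$seed
  )
}
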