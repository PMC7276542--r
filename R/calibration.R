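#' Weighted sum-of-squares error between a trajectory and observations
#'
#' Each observed variable is standardized by its own observed maximum before
#' squaring, so variables spanning different orders of magnitude (mM
#' lactate, headspace gas contents) contribute on a comparable scale; model
#' values are linearly interpolated onto the observation times.
#'
#' @param traj A `tc_trajectory`.
#' @param observations Tibble with columns `time`, `variable`, `value`.
#' @param weights Named per-variable weights (default: 1 for every observed
#'   variable).
#' @return Scalar error (dimensionless).
#' @export
weighted_sse <- function(traj, observations, weights = NULL) {
  vars <- unique(observations$variable)
  if (is.null(weights)) weights <- setNames(rep(1, length(vars)), vars)
  total <- 0
  for (v in vars) {
    w <- weights[[v]] %||% 0
    if (w == 0) next
    o <- observations[observations$variable == v, ]
    m <- trajectory_at(traj, v, o$time)
    s <- max(abs(o$value))
    if (s <= 0) s <- 1
    total <- total + w * sum(((m - o$value) / s)^2)
  }
  total
}

#' Extent and scale of a parameter's effect on the observed variables
#'
#' Perturbs one minimum-energy threshold by `step` in both directions,
#' re-simulates, and reports how many observed variables change by more than
#' `threshold` (relative to each variable's own baseline maximum) and the
#' largest such normalized change.
#'
#' @param parameter `"<population>:<pathway>"` label.
#' @param config A `tc_config` (at the current parameter values).
#' @param observations Observation tibble (defines the observed variables
#'   and times).
#' @param step Perturbation size, kJ mol^-1 (default 5).
#' @param threshold Normalized-change threshold for counting a variable as
#'   affected (default 0.01).
#' @param baseline Optional pre-computed baseline trajectory.
#' @param bounds Parameter bounds the perturbed values are clipped to.
#' @return List with `extent` (count), `scale` (max normalized change) and
#'   `per_variable` (named vector of normalized changes).
#' @export
parameter_effect <- function(parameter, config, observations, step = 5,
                             threshold = 0.01, baseline = NULL,
                             bounds = c(-60, -1)) {
  vars <- unique(observations$variable)
  times <- sort(unique(observations$time))
  if (is.null(baseline)) baseline <- simulate_community(config)
  p0 <- get_dgmin(config, parameter)
  delta <- setNames(numeric(length(vars)), vars)
  for (s in c(-step, step)) {
    p <- min(max(p0 + s, bounds[1]), bounds[2])
    if (p == p0) next
    pert <- tryCatch(
      simulate_community(set_dgmin(config, parameter, p)),
      error = function(e) NULL)
    if (is.null(pert)) next # failed perturbation: parameter deprioritized
    for (v in vars) {
      b <- trajectory_at(baseline, v, times)
      q <- trajectory_at(pert, v, times)
      s0 <- max(abs(b))
      ch <- if (s0 > 0) max(abs(q - b)) / s0 else as.numeric(max(abs(q)) > 0)
      delta[v] <- max(delta[v], ch)
    }
  }
  list(extent = sum(delta > threshold), scale = max(delta, 0),
       per_variable = delta)
}

#' Hierarchical calibration of minimum-energy thresholds
#'
#' Iterative single-parameter fitting: at each step the remaining parameters
#' are ranked by the extent of their effect (fewest observed variables
#' affected first, ties broken by larger scale, then by declaration order);
#' the top parameter is optimized alone by bounded quasi-Newton minimization
#' of [weighted_sse()], with the observed variables weighted by that
#' parameter's own normalized sensitivities; the fitted value is then fixed
#' and the procedure repeats until every parameter is fixed. Whole passes
#' are restarted from jittered starting values (seeded) until the error no
#' longer improves.
#'
#' @param config A `tc_config`.
#' @param observations Tibble `time`, `variable`, `value`.
#' @param parameters Character vector of `"<population>:<pathway>"` labels,
#'   or a tibble with columns `parameter`, `lower`, `upper`, `start`
#'   (defaults -60, -1, -40).
#' @param step,threshold Sensitivity settings passed to
#'   [parameter_effect()].
#' @param outer_tol Stop restarting once the error improves by less than
#'   this fraction (default 1e-3).
#' @param max_outer Maximum number of passes (default 4).
#' @param jitter_sd Standard deviation of the seeded start jitter,
#'   kJ mol^-1.
#' @param seed RNG seed controlling the restarts.
#' @return A `tc_fit`: fitted values, per-iteration trace, weights used;
#'   supports [tidy()] and [glance()].
#' @export
hierarchical_calibrate <- function(config, observations, parameters,
                                   step = 5, threshold = 0.01,
                                   outer_tol = 1e-3, max_outer = 4,
                                   jitter_sd = 5, seed = 1L) {
  if (is.character(parameters)) {
    parameters <- tibble::tibble(parameter = parameters, lower = -60,
                                 upper = -1, start = -40)
  }
  stopifnot(nrow(parameters) >= 1L, all(parameters$upper < 0))
  vars <- unique(observations$variable)
  set.seed(seed)
  trace <- list()
  best <- NULL
  one_pass <- function(starts, pass) {
    cfg <- config
    for (k in seq_len(nrow(parameters))) {
      cfg <- set_dgmin(cfg, parameters$parameter[k], starts[k])
    }
    remaining <- seq_len(nrow(parameters))
    fitted <- setNames(starts, parameters$parameter)
    unident <- character()
    while (length(remaining)) {
      baseline <- simulate_community(cfg)
      effects <- lapply(remaining, function(k) {
        parameter_effect(parameters$parameter[k], cfg, observations,
                         step = step, threshold = threshold,
                         baseline = baseline,
                         bounds = c(parameters$lower[k], parameters$upper[k]))
      })
      extents <- vapply(effects, `[[`, 0, "extent")
      scales <- vapply(effects, `[[`, 0, "scale")
      if (all(extents == 0)) {
        if (length(remaining) == nrow(parameters) && pass == 1L) {
          abort("no parameter affects any observed variable: unidentifiable under provided observations")
        }
        unident <- c(unident, parameters$parameter[remaining])
        break
      }
      ord <- order(extents == 0, extents, -scales, remaining)
      pick <- ord[1]
      k <- remaining[pick]
      eff <- effects[[pick]]
      w <- eff$per_variable
      w <- if (sum(w) > 0) w / sum(w) else setNames(rep(1 / length(vars), length(vars)), vars)
      par_lab <- parameters$parameter[k]
      obj <- function(p) {
        tr <- tryCatch(simulate_community(set_dgmin(cfg, par_lab, p)),
                       error = function(e) NULL)
        if (is.null(tr)) return(1e6)
        weighted_sse(tr, observations, weights = w)
      }
      opt <- optim(fitted[par_lab], obj, method = "L-BFGS-B",
                   lower = parameters$lower[k], upper = parameters$upper[k],
                   control = list(factr = 1e10, parscale = 10))
      fitted[par_lab] <- opt$par
      cfg <- set_dgmin(cfg, par_lab, opt$par)
      trace[[length(trace) + 1L]] <<- tibble::tibble(
        pass = pass, parameter = par_lab, extent = eff$extent,
        scale = eff$scale, value = unname(opt$par),
        objective = unname(opt$value))
      remaining <- remaining[-pick]
    }
    final <- weighted_sse(simulate_community(cfg), observations)
    list(fitted = fitted, error = final, config = cfg, unidentifiable = unident)
  }
  starts <- parameters$start
  for (pass in seq_len(max_outer)) {
    res <- one_pass(starts, pass)
    if (is.null(best) || res$error < best$error) {
      improved <- is.null(best) ||
        (best$error - res$error) > outer_tol * max(best$error, 1e-12)
      best <- res
    } else {
      improved <- FALSE
    }
    if (pass > 1L && !improved) break
    starts <- pmin(pmax(best$fitted + stats::rnorm(nrow(parameters),
                                                   sd = jitter_sd),
                        parameters$lower), parameters$upper)
  }
  structure(list(parameters = best$fitted, error = best$error,
                 unidentifiable = best$unidentifiable,
                 trace = dplyr::bind_rows(trace),
                 observations = observations, config = best$config,
                 seed = seed),
            class = "tc_fit")
}

#' @export
print.tc_fit <- function(x, ...) {
  cat("<calibration fit> weighted error", format(x$error, digits = 4), "\n")
  print(round(x$parameters, 2))
  if (length(x$unidentifiable)) {
    cat("unidentifiable:", paste(x$unidentifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' One-dimensional error-landscape sweep of a threshold parameter
#'
#' Simulates the system over a grid of values of one minimum-energy
#' threshold (all other parameters fixed) and records, for each observed
#' variable and each requested variable subset, the standardized
#' sum-of-squares error against the observations; each error curve is
#' normalized by its own maximum.
#'
#' @param parameter `"<population>:<pathway>"` label.
#' @param grid Numeric vector of threshold values, kJ mol^-1.
#' @param config A `tc_config`.
#' @param observations Tibble `time`, `variable`, `value`.
#' @param subsets Optional named list of variable groups to aggregate
#'   (e.g. `list("acetate+H2" = c("acetate", "H2(g)"))`).
#' @return A `tc_sweep` tibble: `parameter`, `value`, `variable`, `sse`,
#'   `sse_norm` (in `[0, 1]`; `NA` rows mark failed simulations).
#' @export
sweep_dgmin <- function(parameter, grid, config, observations,
                        subsets = NULL) {
  vars <- unique(observations$variable)
  rows <- lapply(grid, function(g) {
    tr <- tryCatch(simulate_community(set_dgmin(config, parameter, g)),
                   error = function(e) NULL)
    per_var <- c(
      setNames(lapply(vars, function(v) v), vars),
      subsets %||% list()
    )
    tibble::tibble(
      parameter = parameter, value = g,
      variable = names(per_var),
      sse = vapply(per_var, function(vs) {
        if (is.null(tr)) return(NA_real_)
        weighted_sse(tr, observations[observations$variable %in% vs, ])
      }, 0)
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(sse_norm = .data$sse / max(.data$sse, na.rm = TRUE)) |>
    dplyr::ungroup()
  class(out) <- c("tc_sweep", class(out))
  out
}

#' Plot an error-landscape sweep
#'
#' @param object A `tc_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tc_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$value, y = .data$sse_norm,
                               colour = .data$variable)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(Delta * G[min] ~ "(kJ/mol)"),
                  y = "normalized error", colour = "error variable")
}
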