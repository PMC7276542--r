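# Shared fixtures, memoized so expensive simulations run once per suite.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

dv_config <- function() memo("dv_config", {
  cfg <- build_dv_mm_mb_system(cultures = "Dv")
  cfg$output_times <- seq(0, 504, by = 4)
  cfg
})

full_config <- function() memo("full_config", build_dv_mm_mb_system())

# Dv monoculture trajectories for the thermodynamic/kinetic contrast
dv_traj_thermo <- function() memo("dv_traj_thermo", {
  simulate_community(set_dgmin(dv_config(), "Dv:lactate_fermentation", -30))
})
dv_traj_kinetic <- function() memo("dv_traj_kinetic", {
  simulate_community(dv_config(), thermodynamics = FALSE)
})

# synthetic observations from a known lactate-fermentation threshold
dv_synth <- function(sigma = 0, seed = 1L) {
  memo(sprintf("dv_synth_%g_%d", sigma, seed), {
    syn <- synthesize_observations(
      dv_config(), c("Dv:lactate_fermentation" = -25),
      variables = c("lactate", "acetate", "H2(g)"),
      sigma = sigma, seed = seed,
      trajectory = memo("dv_truth_traj", {
        simulate_community(set_dgmin(dv_config(),
                                     "Dv:lactate_fermentation", -25))
      }))
    syn
  })
}

# Dv monoculture without sulfate: the sulfate-respiring pathways never run
dv_nosulfate_config <- function() memo("dv_nosulfate", {
  cfg <- build_dv_mm_mb_system(cultures = "Dv", sulfate = 0)
  cfg$initial$totals[["Na"]] <- cfg$initial$totals[["Na"]] - 0.015
  cfg$output_times <- seq(0, 504, by = 8)
  cfg
})
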