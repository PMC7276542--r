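test_that("optical density converts to evenly split biomass", {
  cfg3 <- full_config()
  b3 <- biomass_from_od(0.974, cfg3)
  expect_length(b3, 3)
  expect_equal(sum(b3), exp(5.12 * 0.974 - 4.987) / molar_mass("C1H1.8O0.5N0.2"))
  expect_equal(sum(b3), 0.0406, tolerance = 1e-2)
  expect_equal(unname(b3), rep(sum(b3) / 3, 3))
  b1 <- biomass_from_od(0.974, dv_config())
  expect_equal(unname(b1[1]), sum(b3), tolerance = 1e-12)
  expect_error(biomass_from_od(0, cfg3), "positive")
})

test_that("state derivative decomposes into biochemistry plus transfer", {
  cfg <- dv_config()
  # probe a mid-trajectory state rather than the clean initial one
  w <- trajectory_wide(dv_traj_thermo())
  row <- w[w$time == 96, ]
  state <- unlist(row[, setdiff(names(w), c("time", "pH", "biomass_total"))])
  full <- state_derivative(cfg, state)
  bio <- state_derivative(cfg, state, terms = "biochemistry")
  tra <- state_derivative(cfg, state, terms = "transfer")
  expect_equal(unclass(full), unclass(bio) + unclass(tra), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(attr(full, "pH"), row$pH, tolerance = 1e-6)
})

test_that("transfer-only derivatives equal the two-film law", {
  cfg <- dv_config()
  cfg$initial$biomass <- c(Dv = 0)
  cfg$initial$od600 <- NULL
  cfg$initial$totals[["H2(aq)"]] <- 1e-4
  state <- thermocomm:::initial_state(cfg)
  d <- state_derivative(cfg, state, terms = "transfer")
  ex <- cfg$exchanges[[1]] # the H2 pair
  expect_identical(ex$aqueous, "H2(aq)")
  ref <- transfer_derivatives(1e-4, 0, ex, cfg$geometry)
  expect_equal(d[["H2(aq)"]], ref[["aq"]], tolerance = 1e-12)
  expect_equal(d[["H2(g)"]], ref[["gas"]], tolerance = 1e-12)
  expect_true(all(d[c("lactate", "acetate", "SO4", "X_Dv")] == 0))
})

test_that("a fully quiescent system has a zero derivative", {
  cfg <- dv_config()
  cfg$initial$biomass <- c(Dv = 0)
  cfg$initial$od600 <- NULL
  # no dissolved volatiles anywhere: no transfer disequilibrium
  cfg$initial$totals[c("carbonate", "sulfide", "H2(aq)", "CH4(aq)")] <- 0
  cfg$initial$totals[["Na"]] <- 0.045 # keep the inventory electroneutral
  cfg$initial$totals[["Cl"]] <- cfg$initial$totals[["ammonium"]]
  d <- state_derivative(cfg)
  expect_true(all(abs(d) < 1e-15))
})

test_that("a zero-duration simulation returns the initial state", {
  cfg <- dv_config()
  cfg$duration <- 0
  cfg$output_times <- NULL
  tr <- simulate_community(cfg)
  w <- trajectory_wide(tr)
  expect_equal(nrow(w), 1)
  expect_equal(w$lactate, 0.03)
  expect_equal(w$X_Dv, unname(biomass_from_od(cfg$initial$od600, cfg)))
})

test_that("balanced reactions conserve C, N and S along a trajectory", {
  # methanogen culture fed H2: its catabolic and anabolic reactions balance
  # exactly, and with k_d = 0 no biomass carbon is destroyed by decay
  cfg <- build_dv_mm_mb_system(cultures = "Mm", duration = 240)
  # realistic threshold so hydrogenotrophic methanogenesis actually runs
  cfg <- set_dgmin(cfg, "Mm:hydrogenotrophic_methanogenesis", -25)
  cfg$populations$Mm$k_d <- 0
  cfg$initial$totals[["H2(aq)"]] <- 2e-4
  cfg$initial$gas[["H2(g)"]] <- 8e-3
  tr <- simulate_community(cfg, output_times = seq(0, 240, by = 4))
  w <- trajectory_wide(tr)
  vr <- cfg$geometry$V_g / cfg$geometry$V_aq
  totals <- function(el) {
    n <- w$lactate * 3 * (el == "C") +
      w$acetate * 2 * (el == "C") +
      w$carbonate * (el == "C") +
      w$`CH4(aq)` * (el == "C") +
      w$sulfide * (el == "S") + w$SO4 * (el == "S") +
      w$ammonium * (el == "N") +
      w$X_Mm * (1 * (el == "C") + 0.2 * (el == "N")) +
      vr * (w$`CO2(g)` * (el == "C") + w$`CH4(g)` * (el == "C") +
              w$`H2S(g)` * (el == "S"))
    n
  }
  for (el in c("C", "N", "S")) {
    tot <- totals(el)
    expect_lt(max(abs(tot - tot[1])), 1e-5 * tot[1])
  }
  # methanogenesis actually ran: methane was produced
  expect_gt(max(w$`CH4(g)`), 1e-4)
})

test_that("the known anabolic rounding imbalance accounts for all carbon drift", {
  # Dv-only culture, k_d = 0: the only unbalanced reaction is the anabolic
  # one, which creates 0.05 C-mol per C-mol of biomass formed
  cfg <- build_dv_mm_mb_system(cultures = "Dv", duration = 240)
  cfg$populations$Dv$k_d <- 0
  tr <- simulate_community(cfg, output_times = seq(0, 240, by = 8))
  w <- trajectory_wide(tr)
  vr <- cfg$geometry$V_g / cfg$geometry$V_aq
  carbon <- w$lactate * 3 + w$acetate * 2 + w$carbonate + w$`CH4(aq)` +
    w$X_Dv + vr * (w$`CO2(g)` + w$`CH4(g)`)
  drift <- carbon - carbon[1]
  expected <- 0.05 * (w$X_Dv - w$X_Dv[1])
  expect_lt(max(abs(drift - expected)), 5e-6)
})

test_that("the reference substrate is non-increasing in a single-pathway monoculture", {
  cfg <- build_dv_mm_mb_system(cultures = "Dv", duration = 240)
  cfg$populations$Dv$pathways <- cfg$populations$Dv$pathways["lactate_sulfate_respiration"]
  tr <- simulate_community(cfg, output_times = seq(0, 240, by = 4))
  w <- trajectory_wide(tr)
  expect_true(all(diff(w$lactate) <= 1e-12))
  expect_true(all(diff(w$SO4) <= 1e-12))
})

test_that("halving solver tolerances leaves terminal state essentially unchanged", {
  cfg <- dv_config()
  a <- trajectory_wide(dv_traj_thermo())
  cfg2 <- set_dgmin(cfg, "Dv:lactate_fermentation", -30)
  cfg2$solver$rtol <- cfg$solver$rtol / 2
  cfg2$solver$atol <- cfg$solver$atol / 2
  b <- trajectory_wide(simulate_community(cfg2))
  for (v in c("lactate", "acetate", "H2(g)", "X_Dv")) {
    av <- a[[v]][nrow(a)]; bv <- b[[v]][nrow(b)]
    expect_lt(abs(av - bv) / max(abs(av), 1e-12), 1e-3)
  }
})

test_that("configurations survive a YAML round trip byte-identically", {
  cfg <- full_config()
  p1 <- tempfile(fileext = ".yml"); p2 <- tempfile(fileext = ".yml")
  write_config(cfg, p1)
  cfg2 <- read_config(p1)
  write_config(cfg2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(get_dgmin(cfg2, "Dv:lactate_fermentation"),
               get_dgmin(cfg, "Dv:lactate_fermentation"))
  expect_equal(cfg2$initial$totals, cfg$initial$totals)
})

test_that("configuration validation catches broken references", {
  cfg <- dv_config()
  bad <- cfg
  bad$initial$totals <- bad$initial$totals[names(bad$initial$totals) != "SO4"]
  expect_error(validate_config(bad, quiet = TRUE), "SO4")
  bad2 <- cfg
  names(bad2$initial$gas)[1] <- "Xe(g)"
  expect_error(validate_config(bad2, quiet = TRUE), "Xe")
  expect_warning(validate_config(cfg, balance_tol = 1e-3), "imbalance")
})
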