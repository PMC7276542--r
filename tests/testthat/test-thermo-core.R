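test_that("molar mass reproduces the biomass carbon-mole weight", {
  expect_equal(signif(molar_mass("C1H1.8O0.5N0.2"), 3), 24.6)
  expect_equal(molar_mass("H2O"), 18.02, tolerance = 1e-3)
  expect_error(molar_mass("Xx2O"), "unknown element")
  expect_error(parse_composition(c(C = 0, H = 0)), "at least one element")
})

test_that("composition parsing handles fractional and implicit counts", {
  expect_equal(parse_composition("C1H1.8O0.5N0.2")[c("C", "H", "N", "O")],
               c(C = 1, H = 1.8, N = 0.2, O = 0.5))
  expect_equal(unname(parse_composition("CH4")["H"]), 4)
  expect_equal(unname(parse_composition("SO4")["S"]), 1)
})

clone_species <- function(sp, from, to) {
  r <- sp[sp$name == from, ]
  r$name <- to
  dplyr::bind_rows(sp, r)
}

test_that("standard reaction energy is a stoichiometry-linear functional", {
  sp <- default_species()
  # identity-like reaction (same substance in and out) has zero energy
  rx0 <- reaction(c("acetate" = -1, "acetate_b" = 1))
  sp2 <- clone_species(sp, "acetate", "acetate_b")
  expect_equal(standard_reaction_energy(rx0, sp2, 310.15), 0)
  # doubling coefficients doubles the energy
  rx <- reaction(c("lactate" = -1, "H2O" = -2, "acetate" = 1, "H2(aq)" = 2,
                   "HCO3" = 1, "H+" = 1), reference = "lactate")
  rx2 <- reaction(rx$coeffs * 2)
  expect_equal(standard_reaction_energy(rx2, sp, 310.15),
               2 * standard_reaction_energy(rx, sp, 310.15))
  # at the reference temperature the Gibbs-Helmholtz form is inactive
  g <- sum(rx$coeffs * vapply(names(rx$coeffs), function(nm) {
    if (nm == "H+") 0 else sp$dGf0[match(nm, sp$name)]
  }, 0))
  expect_equal(standard_reaction_energy(rx, sp, 298.15), g)
  # a species without formation energy is a hard error naming it
  sp3 <- sp
  sp3$dGf0[sp3$name == "acetate"] <- NA
  expect_error(standard_reaction_energy(rx, sp3), "acetate")
})

test_that("concentration dependence follows RT ln Q exactly", {
  sp <- default_species()
  set.seed(42)
  pool <- c("lactate", "acetate", "HCO3", "H2(aq)", "SO4", "H2S(aq)",
            "CH4(aq)", "NH4")
  for (i in 1:20) {
    nm <- sample(pool, sample(2:5, 1))
    nu <- setNames(round(runif(length(nm), -2, 2), 2), nm)
    nu <- nu[nu != 0]
    if (length(nu) < 2) next
    rx <- reaction(nu)
    act <- setNames(10^runif(length(nu), -6, -1), names(nu))
    lhs <- reaction_energy(rx, sp, act, pH = 7, temperature = 310.15) -
      reaction_energy(rx, sp, pH = 7, temperature = 310.15)
    rhs <- 8.314462618e-3 * 310.15 * sum(nu * log(act))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("reaction energies are additive and monotone in ln Q", {
  sp <- default_species()
  fer <- reaction(c("lactate" = -1, "H2O" = -2, "acetate" = 1, "H2(aq)" = 2,
                    "HCO3" = 1, "H+" = 1))
  h2s <- reaction(c("H2(aq)" = -2, "SO4" = -0.5, "H+" = -1,
                    "H2S(aq)" = 0.5, "H2O" = 2))
  summed <- reaction(c("lactate" = -1, "SO4" = -0.5, "acetate" = 1,
                       "HCO3" = 1, "H2S(aq)" = 0.5))
  act <- c("lactate" = 0.03, "acetate" = 0.01, "H2(aq)" = 1e-6,
           "HCO3" = 0.03, "SO4" = 0.0075, "H2S(aq)" = 1e-3)
  e <- function(rx) reaction_energy(rx, sp, act, pH = 7.2, temperature = 310.15)
  expect_equal(e(fer) + e(h2s), e(summed), tolerance = 1e-10)
  # raising a product activity raises dG
  act_hi <- act; act_hi[["acetate"]] <- 0.1
  expect_gt(reaction_energy(summed, sp, act_hi, 7.2, 310.15), e(summed))
  # zero activity is rejected, the floor is the caller's job
  act_bad <- act; act_bad[["acetate"]] <- 0
  expect_error(reaction_energy(summed, sp, act_bad, 7.2, 310.15),
               "non-positive activity")
})

test_that("balance_check flags the known rounding imbalance and passes balanced reactions", {
  sp <- default_species()
  mm_ana <- reaction(c("HCO3" = -1, "H2(aq)" = -2.1, "NH4" = -0.2,
                       "H+" = -0.8, "biomass" = 1, "H2O" = 2.5))
  bal <- balance_check(mm_ana, sp)
  expect_true(all(abs(bal$imbalance) < 1e-6))
  expect_false(any(bal$flagged))
  # the printed Dv anabolic stoichiometry creates ~0.05 C per biomass
  dv_ana <- reaction(c("lactate" = -0.35, "NH4" = -0.2, "H+" = -0.1,
                       "biomass" = 1, "acetate" = 0.05, "H2O" = 0.4))
  bal2 <- balance_check(dv_ana, sp)
  expect_equal(bal2$imbalance[bal2$quantity == "C"], 0.05, tolerance = 1e-9)
  expect_equal(bal2$imbalance[bal2$quantity == "H"], 0.10, tolerance = 1e-9)
  expect_equal(bal2$imbalance[bal2$quantity == "charge"], 0, tolerance = 1e-9)
  # identity reaction balances trivially
  sp2 <- clone_species(sp, "acetate", "acetate_b")
  ident <- balance_check(reaction(c("acetate" = -1, "acetate_b" = 1)), sp2)
  expect_true(all(ident$imbalance == 0))
  expect_false(any(ident$flagged))
})
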