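sp <- default_species()

test_that("dynamic stoichiometry factor and yield arithmetic", {
  expect_equal(lambda_cat(-228.2, 18.11, -170.17), 1.447, tolerance = 1e-3)
  expect_equal(lambda_cat(-876.4, -64.73, -48.12), 16.87, tolerance = 1e-3)
  expect_equal(lambda_cat(-50, -50, -10), 0)
  expect_error(lambda_cat(-228.2, 18.11, 5), "dG_cat")
  expect_equal(growth_yield(1.447, 0.35), 0.5565, tolerance = 1e-3)
  expect_equal(growth_yield(1, 0), 1)
  expect_error(growth_yield(-1, 0.5))
  # yield strictly decreases with the catabolic draw
  y <- vapply(seq(0.5, 20, by = 0.5), growth_yield, 0, gamma_D = 0.35)
  expect_true(all(diff(y) < 0))
})

test_that("Monod factor is the product over declared limiting substrates", {
  expect_equal(kinetic_factor(c(S = 1e-3), c(S = 1e-3)), 0.5)
  expect_equal(kinetic_factor(c(S = 1e6), c(S = 1e-3)), 1, tolerance = 1e-8)
  expect_equal(kinetic_factor(c(A = 1e-3, B = 2e-4), c(A = 1e-3, B = 2e-4)),
               0.25)
  expect_equal(kinetic_factor(c(A = 0, B = 1), c(A = 1e-3)), 0)
  expect_error(kinetic_factor(c(A = 1e-3), c(A = 1e-3, B = 2e-4)),
               "no concentration")
})

test_that("thermodynamic factor has an exact threshold and closed form", {
  rt <- 8.314462618e-3 * 310.15
  expect_equal(thermodynamic_factor(-30, -30, 310.15), 0)
  expect_equal(thermodynamic_factor(-20, -30, 310.15), 0)
  expect_equal(thermodynamic_factor(-30 - rt * log(2), -30, 310.15), 0.5)
  expect_gt(thermodynamic_factor(-300, -30, 310.15), 0.999)
  f <- vapply(seq(-60, -10, by = 1), thermodynamic_factor, 0,
              dG_min = -30, temperature = 310.15)
  expect_true(all(f >= 0 & f < 1))
})

dv_pw <- catabolic_pathway(
  "lactate_fermentation",
  reaction(c("lactate" = -1, "H2O" = -2, "acetate" = 1, "H2(aq)" = 2,
             "HCO3" = 1, "H+" = 1), reference = "lactate"),
  v_max = 0.5, K_S = c("lactate" = 1.3e-3), dG_min = -30, dG_met = -265.1)
dv_ana <- anabolic_reaction(
  reaction(c("lactate" = -0.35, "NH4" = -0.2, "H+" = -0.1, "biomass" = 1,
             "acetate" = 0.05, "H2O" = 0.4)), donor = "lactate")

test_that("pathway state couples rate, threshold and energy balance", {
  conc <- c("lactate" = 0.03, "acetate" = 1e-6, "H2(aq)" = 1e-9,
            "HCO3" = 0.03, "NH4" = 5e-3)
  st <- pathway_specific_rate(dv_pw, dv_ana, sp, conc, pH = 7,
                              temperature = 310.15)
  expect_lt(st$dG_cat, -30)      # products near zero: far from equilibrium
  expect_gt(st$rate, 0)
  expect_lte(st$rate, dv_pw$v_max)
  expect_gt(st$lambda, 0)
  expect_equal(st$yield, 1 / (st$lambda + 0.35))
  # driving the products up to the threshold shuts the pathway down
  conc_hi <- c("lactate" = 0.03, "acetate" = 0.05, "H2(aq)" = 0.05,
               "HCO3" = 0.05, "NH4" = 5e-3)
  st_hi <- pathway_specific_rate(dv_pw, dv_ana, sp, conc_hi, pH = 7,
                                 temperature = 310.15)
  expect_gte(st_hi$dG_cat, -30)
  expect_equal(st_hi$rate, 0)
  expect_true(is.na(st_hi$lambda))
  # zero substrate: rate is zero regardless of energetics
  conc0 <- conc; conc0[["lactate"]] <- 0
  expect_equal(pathway_specific_rate(dv_pw, dv_ana, sp, conc0, 7, 310.15)$rate, 0)
  # forcing F_T to one recovers the pure forward-kinetics rate
  st_fwd <- pathway_specific_rate(dv_pw, dv_ana, sp, conc_hi, 7, 310.15,
                                  thermodynamics = FALSE)
  expect_equal(st_fwd$F_T, 1)
  expect_gt(st_fwd$rate, 0)
})

test_that("yield rises as catabolism becomes more exergonic", {
  conc <- c("lactate" = 0.03, "acetate" = 1e-4, "HCO3" = 0.03, "NH4" = 5e-3)
  ylds <- vapply(c(1e-4, 1e-6, 1e-8, 1e-10), function(h2) {
    st <- pathway_specific_rate(dv_pw, dv_ana, sp,
                                c(conc, "H2(aq)" = h2), 7, 310.15)
    st$yield
  }, 0)
  expect_true(all(diff(ylds) > 0))
})

test_that("community derivatives reduce to Monod growth when saturated and unconstrained", {
  pop <- population("Dv", list(dv_pw), dv_ana, k_d = 8.33e-4)
  conc <- c("lactate" = 0.5, "acetate" = 1e-9, "H2(aq)" = 1e-12,
            "HCO3" = 1e-3, "NH4" = 5e-3)
  d <- community_derivatives(list(pop), sp, conc, c(Dv = 1e-3), pH = 7,
                             temperature = 310.15)
  st <- d$pathway_states
  mu_expected <- dv_pw$v_max * st$F_D * st$F_T / st$lambda - 8.33e-4
  expect_equal(d$biomass[["Dv"]] / 1e-3, mu_expected, tolerance = 1e-12)
  expect_gt(st$F_D, 0.99)
  expect_gt(st$F_T, 0.99)
  # zero biomass: every derivative vanishes
  d0 <- community_derivatives(list(pop), sp, conc, c(Dv = 0), 7, 310.15)
  expect_true(all(d0$species == 0) && all(d0$biomass == 0))
})

test_that("community derivatives match a hand-expanded two-population oracle", {
  mm_pw <- catabolic_pathway(
    "hydrogenotrophic_methanogenesis",
    reaction(c("HCO3" = -0.25, "H2(aq)" = -1, "H+" = -0.25,
               "CH4(aq)" = 0.25, "H2O" = 0.75), reference = "H2(aq)"),
    v_max = 2, K_S = c("H2(aq)" = 6e-6), dG_min = -30, dG_met = -876.4)
  mm_ana <- anabolic_reaction(
    reaction(c("HCO3" = -1, "H2(aq)" = -2.1, "NH4" = -0.2, "H+" = -0.8,
               "biomass" = 1, "H2O" = 2.5)), donor = "H2(aq)")
  pops <- list(population("Dv", list(dv_pw), dv_ana, k_d = 8.33e-4),
               population("Mm", list(mm_pw), mm_ana, k_d = 8.33e-4))
  conc <- c("lactate" = 0.02, "acetate" = 3e-3, "H2(aq)" = 2e-5,
            "HCO3" = 0.03, "CH4(aq)" = 1e-4, "NH4" = 5e-3)
  x <- c(Dv = 4e-4, Mm = 2e-4)
  d <- community_derivatives(pops, sp, conc, x, pH = 7.1, temperature = 310.15)

  # independent, fully spelled-out re-derivation
  rt <- 8.314462618e-3 * 310.15
  e <- function(rx) reaction_energy(rx, sp, pmax(conc, 1e-12), 7.1, 310.15)
  oracle <- setNames(numeric(length(d$species)), names(d$species))
  ob <- c(Dv = 0, Mm = 0)
  for (i in 1:2) {
    pop <- pops[[i]]
    pw <- pop$pathways[[1]]
    dgc <- e(pw$rxn); dga <- e(pop$anabolic$rxn)
    fd <- prod(conc[names(pw$K_S)] / (pw$K_S + conc[names(pw$K_S)]))
    ft <- 1 - exp(min(0, dgc - pw$dG_min) / rt)
    r <- pw$v_max * fd * ft
    lam <- (pw$dG_met - dga) / dgc
    for (nm in setdiff(names(pw$rxn$coeffs), c("H+", "H2O"))) {
      oracle[nm] <- oracle[nm] + x[[i]] * r * pw$rxn$coeffs[[nm]]
    }
    for (nm in setdiff(names(pop$anabolic$rxn$coeffs),
                       c("H+", "H2O", "biomass"))) {
      oracle[nm] <- oracle[nm] + x[[i]] * (r / lam) * pop$anabolic$rxn$coeffs[[nm]]
    }
    ob[[i]] <- x[[i]] * (r / lam - 8.33e-4)
  }
  expect_equal(d$species[names(oracle)], oracle, tolerance = 1e-12)
  expect_equal(d$biomass, ob, tolerance = 1e-12)
})
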