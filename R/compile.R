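# Internal: pre-compile a configuration into flat index/coefficient
# structures so that the ODE right-hand side is cheap to evaluate. All
# formation energies are folded into per-reaction standard energies at the
# system temperature; speciation and charge balance operate on integer
# indices into one "free species" vector.
compile_system <- function(config, thermodynamics = TRUE) {
  sp <- config$species
  temp <- config$geometry$temperature
  rt <- .RGAS * temp

  aq_pools <- names(config$initial$totals)
  gas_pools <- names(config$initial$gas)
  pop_names <- names(config$populations)
  bio_pools <- paste0("X_", pop_names)
  pools <- c(aq_pools, gas_pools, bio_pools)
  n_aq <- length(aq_pools); n_gas <- length(gas_pools); n_bio <- length(bio_pools)

  # free aqueous species: family members + standalone pools
  standalone <- setdiff(aq_pools, names(config$families))
  free_names <- c(unlist(lapply(config$families, `[[`, "members")), standalone)
  free_names <- unname(free_names)
  free_idx <- setNames(seq_along(free_names), free_names)
  pool_of_free <- integer(length(free_names))
  charges <- numeric(length(free_names))
  for (nm in free_names) {
    charges[free_idx[nm]] <- species_row(sp, nm)$charge
  }
  fam_list <- list()
  for (f in config$families) {
    idx <- free_idx[f$members]
    pool_of_free[idx] <- match(f$name, pools)
    fam_list[[f$name]] <- list(idx = unname(idx), pK = f$pK,
                               pool = match(f$name, pools))
  }
  for (nm in standalone) {
    pool_of_free[free_idx[nm]] <- match(nm, pools)
  }

  speciate <- function(totals, pH) {
    free <- numeric(length(free_names))
    free[free_idx[standalone]] <- totals[match(standalone, aq_pools)]
    for (f in fam_list) {
      expo <- c(0, cumsum(pH - f$pK))
      expo <- expo - max(expo)
      w <- 10^expo
      free[f$idx] <- totals[f$pool] * w / sum(w)
    }
    free
  }

  pKw <- config$solver$pKw
  charge_fn <- function(totals, pH) {
    sum(speciate(totals, pH) * charges) + 10^(-pH) - 10^(pH - pKw)
  }

  # warm-started Brent solve of the (monotone-decreasing) charge balance
  ph_env <- new.env(parent = emptyenv())
  ph_env$last <- 7
  solve_ph_fast <- function(totals) {
    f <- function(p) charge_fn(totals, p)
    lo <- max(0, ph_env$last - 0.3); hi <- min(14, ph_env$last + 0.3)
    flo <- f(lo); fhi <- f(hi)
    while (flo < 0 && lo > 0) { lo <- max(0, lo - 1); flo <- f(lo) }
    while (fhi > 0 && hi < 14) { hi <- min(14, hi + 1); fhi <- f(hi) }
    if (sign(flo) == sign(fhi)) {
      abort(sprintf("charge balance has no root in pH [0, 14] (residuals %.3e, %.3e)",
                    flo, fhi))
    }
    p <- uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 1e-11)$root
    ph_env$last <- p
    p
  }

  compile_rxn <- function(rxn, drop = character()) {
    nm <- names(rxn$coeffs)
    keep <- !(nm %in% c("H+", "H2O", drop))
    spec_names <- nm[keep]
    bad <- setdiff(spec_names, free_names)
    if (length(bad)) {
      abort(sprintf("reaction species not pooled: %s", paste(bad, collapse = ", ")))
    }
    idx <- unname(free_idx[spec_names])
    nu <- unname(rxn$coeffs[keep])
    stoich <- numeric(length(pools))
    for (k in seq_along(idx)) {
      p <- pool_of_free[idx[k]]
      stoich[p] <- stoich[p] + nu[k]
    }
    h_coef <- if ("H+" %in% nm) rxn$coeffs[["H+"]] else 0
    dg0 <- standard_reaction_energy(rxn, sp, temp)
    list(idx = idx, nu = nu, h_coef = h_coef, dg0 = dg0, stoich = stoich)
  }

  pops <- lapply(config$populations, function(pop) {
    ana <- compile_rxn(pop$anabolic$rxn, drop = pop$anabolic$biomass)
    pws <- lapply(pop$pathways, function(pw) {
      c(compile_rxn(pw$rxn),
        list(name = pw$name, v_max = pw$v_max,
             ks_idx = unname(free_idx[names(pw$K_S)]),
             ks = unname(pw$K_S), dG_min = pw$dG_min, dG_met = pw$dG_met))
    })
    list(name = pop$name, k_d = pop$k_d, ana = ana,
         gamma_D = pop$anabolic$gamma_D, pathways = pws)
  })

  exch <- lapply(config$exchanges, function(e) {
    list(aq_idx = unname(free_idx[e$aqueous]),
         aq_pool = pool_of_free[free_idx[e$aqueous]],
         gas_pool = match(e$gas, pools),
         kLa = e$kLa,
         ceq_fac = henry_at_temperature(e, temp) * .RGAS_J * temp,
         vratio = config$geometry$V_aq / config$geometry$V_g)
  })

  floor_ <- config$solver$conc_floor
  ln10mph <- function(pH) log(10) * (-pH)

  derivative <- function(y, terms = "all") {
    y <- pmax(y, 0)
    totals <- y[seq_len(n_aq)]
    gas <- y[n_aq + seq_len(n_gas)]
    bio <- y[n_aq + n_gas + seq_len(n_bio)]
    pH <- solve_ph_fast(totals)
    free <- speciate(totals, pH)
    lnact <- log(pmax(free, floor_))
    lhp <- ln10mph(pH)
    d <- numeric(length(pools))
    if (terms %in% c("all", "biochemistry")) {
      for (ip in seq_along(pops)) {
        pop <- pops[[ip]]
        x <- bio[ip]
        ana <- pop$ana
        dg_an <- ana$dg0 + rt * (sum(ana$nu * lnact[ana$idx]) + ana$h_coef * lhp)
        growth <- 0
        for (pw in pop$pathways) {
          fd <- prod(free[pw$ks_idx] / (pw$ks + free[pw$ks_idx]))
          if (fd <= 0 && thermodynamics) next
          dg_cat <- pw$dg0 + rt * (sum(pw$nu * lnact[pw$idx]) + pw$h_coef * lhp)
          ft <- if (thermodynamics) {
            1 - exp(min(0, dg_cat - pw$dG_min) / rt)
          } else 1
          r <- pw$v_max * fd * ft
          if (r <= 0 || x <= 0) next
          d <- d + (x * r) * pw$stoich
          couple <- if (thermodynamics) TRUE else dg_cat < 0
          if (couple && dg_cat < 0) {
            lam <- (pw$dG_met - dg_an) / dg_cat
            if (lam > 0) {
              d <- d + (x * r / lam) * ana$stoich
              growth <- growth + r / lam
            }
          }
        }
        ib <- n_aq + n_gas + ip
        d[ib] <- d[ib] + x * (growth - pop$k_d)
      }
    }
    if (terms %in% c("all", "transfer")) {
      for (e in exch) {
        drive <- free[e$aq_idx] - e$ceq_fac * gas[e$gas_pool - n_aq]
        d[e$aq_pool] <- d[e$aq_pool] - e$kLa * drive
        d[e$gas_pool] <- d[e$gas_pool] + e$kLa * e$vratio * drive
      }
    }
    # pools at the floor cannot be driven further negative
    neg <- y <= 0 & d < 0
    d[neg] <- 0
    list(d = d, pH = pH)
  }

  list(pools = pools, n_aq = n_aq, n_gas = n_gas, n_bio = n_bio,
       aq_pools = aq_pools, gas_pools = gas_pools, bio_pools = bio_pools,
       free_names = free_names, free_idx = free_idx,
       speciate = speciate, solve_ph = solve_ph_fast, charge_fn = charge_fn,
       derivative = derivative, pops = pops, temperature = temp,
       ph_env = ph_env)
}

# initial state vector (named, in pool order) from a config
initial_state <- function(config, sys = NULL) {
  if (is.null(sys)) sys <- compile_system(config)
  bio <- config$initial$biomass
  if (is.null(bio)) {
    bio <- biomass_from_od(config$initial$od600, config)
  }
  bio <- bio[names(config$populations)]
  y0 <- c(config$initial$totals[sys$aq_pools],
          config$initial$gas[sys$gas_pools],
          setNames(as.numeric(bio), sys$bio_pools))
  setNames(as.numeric(y0), sys$pools)
}
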