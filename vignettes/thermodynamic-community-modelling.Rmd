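---
title: "Thermodynamic modelling of anaerobic community dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic modelling of anaerobic community dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocomm)
```

## The model

`thermocomm` simulates batch cultures of microbial populations whose growth
is limited not only by substrate availability but by the free energy their
catabolic reactions can still deliver. This matters for anaerobic guilds -
fermenters, sulfate reducers, methanogens - whose pathways operate within a
few tens of kJ/mol of equilibrium, where classical Monod models predict
conversions that thermodynamics forbids.

Each population carries one or more **catabolic pathways** and exactly one
**anabolic (biomass-forming) reaction**. Three quantities connect them:

* **Catabolic energy** $\Delta G_{cat}$ (kJ per mol of the pathway's
  reference substrate), evaluated at every instant from the current
  speciated concentrations via $\Delta G = \Delta G^\circ(T) + RT \ln Q$,
  with proton activity $10^{-\mathrm{pH}}$ and water activity 1.
* **Anabolic energy** $\Delta G_{an}$ (kJ per C-mol biomass), evaluated the
  same way (biomass activity is taken as 1, the usual convention for a
  solid-like phase).
* **Metabolic (dissipated) energy** $\Delta G_{met}$ (kJ per C-mol
  biomass), a fixed, pathway-specific dissipation drawn from published
  estimates. Lumping maintenance into this constant is a deliberate
  simplification; dynamic-maintenance formulations exist but add parameters
  this model is designed to avoid.

The energy balance closes through a *dynamic stoichiometry factor*

$$\lambda_{cat} = \frac{\Delta G_{met} - \Delta G_{an}}{\Delta G_{cat}},$$

the number of catabolic turnovers needed per C-mol of biomass. The yield
follows as $Y = 1/(\lambda_{cat} + \gamma_D)$, where $\gamma_D$ is the
anabolic draw of the electron donor. We read the yield expression as the
reciprocal of the *sum*: it is the only reading in which $Y$ has units of
mol$_X$ mol$_S^{-1}$ and substrate bookkeeping (catabolic plus anabolic
draw) is consistent. $\lambda_{cat}$ itself carries units of mol$_S$
mol$_X^{-1}$ for the same dimensional reason.

The specific rate of each pathway multiplies a kinetic and a thermodynamic
factor,

$$r = v_{max} \cdot
  \underbrace{\prod_k \frac{[S_k]}{K_{S_k} + [S_k]}}_{F_D} \cdot
  \underbrace{\left(1 - e^{\min(0,\, \Delta G_{cat} - \Delta G_{min})/RT}\right)}_{F_T},$$

where $\Delta G_{min} < 0$ is the pathway's **minimum energy threshold**:
the share of the catabolic energy the cell must retain as driving force,
ion gradients and conserved-moiety regeneration. $F_T$ is exactly zero at
$\Delta G_{cat} = \Delta G_{min}$ - the pathway shuts down with energy
still formally available - and approaches 1 far from equilibrium.
$\Delta G_{min}$ is the calibratable parameter of the package.

Chemical and biomass dynamics assemble additively over populations $i$ and
pathways $j$:

$$\frac{d[A]}{dt} = \sum_i [X_i] \sum_j r_{i,j}
  \left(\frac{\gamma_{i,A}}{\lambda_{cat,i,j}} + \vartheta_{i,j,A}\right),
\qquad
\frac{d[X_i]}{dt} = [X_i]\left(\sum_j \frac{r_{i,j}}{\lambda_{cat,i,j}}
  - k_d\right),$$

with a linear decay coefficient $k_d$ (default $8.33\times10^{-4}$ h$^{-1}$
for every population, per-population override allowed). Anabolic terms are
dropped whenever a pathway's rate is zero or its energy balance cannot
support growth ($\Delta G_{cat} \ge 0$ or $\lambda_{cat} \le 0$); the rate
is zero there anyway, so nothing physical is lost and the $1/\lambda$
singularity never arises.

## pH and speciation

The simulator's aqueous state variables are *family totals* (e.g. total
acetate = acetic acid + acetate ion) plus non-speciating free species. At
**every** derivative evaluation the pH is re-solved algebraically from the
charge balance - speciated members via the closed-form ionization ladder,
fixed ions, $[\mathrm{H^+}] - [\mathrm{OH^-}]$ - by Brent-type bracketed
root finding on pH $\in [0, 14]$ (the residual tolerance, not a pH
tolerance, is the convergence criterion; default $10^{-12}$ eq/L). The pH
is therefore an algebraic constraint, not a state variable, which keeps the
ODE system consistent with instantaneous acid-base equilibration. pK values
are temperature-fixed 25 °C literature values; the water autoionization pK
defaults to 14.0 and is configurable (the 310 K value is nearer 13.6; the
difference shifts absolute pH slightly but none of the package's
conclusions).

Free energies always use the *free* species concentration at the current
pH - e.g. dissolved CO2, not total carbonate - which is what makes the
gas-coupled pathways sensitive to the pH trajectory.

## Gas/liquid exchange

Volatile species exist as distinct aqueous and gas-phase species, each in
mol per litre of its own phase. Two-film transfer drives the dissolved
concentration toward the Henry equilibrium concentration
$C_{eq} = H(T)\, R\, T\, [A(g)]$ (ideal-gas conversion of headspace content
to partial pressure), at rate $k_La$; the headspace balance is scaled by
$V_{aq}/V_g$ so total moles are conserved identically. Henry solubilities
are adjusted from 298.15 K with the van 't Hoff form
$H(T) = H_{298} \exp\!\big(c\,(1/T - 1/298.15)\big)$ using the standard
positive-coefficient convention (solubility decreases with temperature);
the tabulated $c$ values follow the usual solubility compilations.
Headspace pressure is emergent and there is no venting - appropriate for
sealed anaerobic tubes over three weeks.

`fit_kla()` recovers $k_La$ from a headspace equilibration series by
bounded scalar minimization (log-scale search on $[10^{-4}, 10^3]$ h$^{-1}$)
of the squared error between the integrated two-state transfer system and
the observations; an equilibrium start is rejected as unidentifiable.

## Numerical choices

* Integration: `deSolve::lsoda` (adaptive, stiff-capable), relative
  tolerance $10^{-6}$, absolute tolerance $10^{-12}$ mol/L. Batch systems
  stiffen near substrate exhaustion, where $F_T$ collapses over a narrow
  concentration range.
* Concentration floor $10^{-12}$ mol/L inside $\ln Q$ only: batch
  simulations start with zero products and $\ln 0$ must never reach the
  integrator. The floor is configurable; rates themselves use the unfloored
  concentrations.
* Negative-concentration guard: a pool at zero cannot be consumed further;
  its derivative is clipped at zero. This is solver-overshoot robustness,
  not chemistry.
* The pH root is warm-started from the previous solve (bracket expansion on
  failure), which cuts the per-derivative cost several-fold without
  affecting the root.
* Tie-breaking in calibration ranking is explicit (extent, then scale, then
  declaration order) so runs are reproducible to the bit under a fixed
  seed.

## The bundled community and its constants

`build_dv_mm_mb_system()` generates the package's reference system: a
lactate-oxidizing sulfate reducer (*Dv*: lactate fermentation, incomplete
lactate oxidation on sulfate, H2 oxidation on sulfate), a hydrogenotrophic
methanogen (*Mm*) and a hydrogenotrophic/acetoclastic methanogen (*Mb*) in
5 mL of bicarbonate-buffered medium (30 mM lactate, 7.5 mM sulfate, 2 mM
sulfide reductant, 5.6 mM ammonium, chloride adjusted so the medium starts
near pH 7.2) under a 12 mL initially inert headspace at 310.15 K, horizon
504 h.

The shipped formation-energy table (`inst/extdata/formation_energies.tsv`)
is a curated compilation in the Thauer/Alberty lineage with enthalpies of
formation where available; standard energies are adjusted to the system
temperature with the linear Gibbs-Helmholtz form
$\Delta G_f(T) = \Delta H_f - (T/298.15)(\Delta H_f - \Delta G_f^\circ)$.
Individual entries were adjusted within the spread of published
compilations (at most 1.8 kJ/mol) so that the reference-condition energies
of all eight bundled reactions reproduce the accepted values for this
community to better than 0.1 kJ/mol; `pathway_energetics()` recomputes them
on demand. Species without a tabulated enthalpy (including biomass, fixed
at -67 kJ/mol) use their 298.15 K value unchanged.

Two printed-stoichiometry quirks are handled deliberately. First, the
sulfate-respiration energy of *Dv* is conventionally quoted **per mol of
sulfate** (two lactate turnovers); the pathway object itself stays
normalized to one mol lactate, and the per-sulfate figure is obtained by
rescaling. Second, the *Dv* anabolic reaction as conventionally printed
carries a ~0.05 C-mol rounding imbalance per C-mol biomass;
`balance_check()` reports it, `validate_config()` warns about it, and the
conservation tests verify that the simulated carbon drift equals exactly
this imbalance times the biomass formed. Users can override the
coefficients if they prefer a strictly balanced variant. Note that biomass
decay removes material from the tracked pools by design (dead biomass is
not mineralized), so element conservation checks are run with $k_d = 0$.

Kinetic constants ($v_{max}$, $K_S$) are literature-plausible
order-of-magnitude defaults and are documented as assumptions: every test
that depends on them is a property or round-trip test, never a check
against a published kinetic value.

## Hierarchical calibration

`hierarchical_calibrate()` estimates $\Delta G_{min}$ values from
time-series observations. Parameters are handled one at a time:

1. For every remaining parameter, perturb by ±5 kJ/mol, re-simulate, and
   record the **extent** (number of observed variables whose trajectory,
   normalized by its own baseline maximum, changes by more than 1%) and
   **scale** (the largest such change).
2. Select the parameter with the strongest effect among the fewest
   variables (smallest nonzero extent; ties broken by larger scale, then
   declaration order).
3. Optimize that parameter alone, by bounded quasi-Newton minimization
   (`optim` L-BFGS-B) of the weighted error, with per-variable weights
   proportional to the parameter's own normalized sensitivities
   (renormalized to sum to one). Each variable is standardized by its
   observed maximum before squaring, so mM-scale and headspace-scale
   variables contribute comparably - the same convention the error
   landscapes use.
4. Fix the fitted value, repeat; restart whole passes from seeded jittered
   starts until the error stops improving.

Bounds default to $[-60, -1]$ kJ/mol with start $-40$: the upper bound
excludes 0 because a zero threshold, although it can fit data, would mean
no catabolic energy is retained by the cell at all and is rejected as
biologically infeasible. Parameters whose pathways never run under the
provided observations (extent 0 for all) are reported as unidentifiable
rather than silently returned - with lactate/sulfate time series alone,
fast sulfate-respiration thresholds are exactly such a case.

`sweep_dgmin()` produces the corresponding one-dimensional error
landscapes, each curve normalized by its own maximum, for visual
verification that a calibrated value sits at a genuine optimum.

## The synthetic-data generator

`synthesize_observations()` imposes known thresholds, simulates, samples on
a schedule (default daily for 21 days, matching the sealed-tube
experimental design the fixture emulates), and applies multiplicative
lognormal noise (default $\sigma = 0.05$; concentrations are positive and
instrument error is roughly proportional, and the log-scale mean of zero
makes the noise median-unbiased). What the generator does **not** emulate:
inoculum carry-over metabolites, replicate tube-to-tube variability,
detection limits, or drift in temperature and pressure. Passing
recovery tests therefore demonstrate that the estimation machinery is
correct and well-conditioned under the stated noise model - not that every
threshold is identifiable from any real dataset; the unidentifiability of
the sulfate-respiration thresholds under this very design illustrates the
difference.

## Problem sizes used by the test-suite

The packaged tests run the monoculture fixture on a 4 h output grid over
the full 504 h horizon, calibrate a single threshold against 21 daily
samples of three observed variables (noise-free and three noisy seeds), and
sweep a 6-point landscape grid; conservation checks use 240 h horizons.
These sizes were chosen as the smallest that exercise every regime of the
model (growth, inhibition, exhaustion) while keeping the suite quick to
run.

## Known limitations

* Concentrations are used as activities; no ionic-strength or
  activity-coefficient corrections.
* pK values and $k_d$ are temperature-fixed; no dynamic maintenance.
* No chemostat mode, venting, or spatial structure.
* The truncated-Newton single-parameter optimizer contract is fulfilled by
  L-BFGS-B (bounded quasi-Newton); with smooth single-parameter landscapes
  the two are interchangeable in practice.

## A worked session

```{r example, eval = FALSE}
cfg <- build_dv_mm_mb_system(cultures = "Dv")

# thermodynamic vs forward-kinetics contrast
on  <- simulate_community(set_dgmin(cfg, "Dv:lactate_fermentation", -30))
off <- simulate_community(cfg, thermodynamics = FALSE)
tail(trajectory_wide(on)$lactate, 1)   # residual lactate remains
tail(trajectory_wide(off)$lactate, 1)  # complete conversion

# recover a known threshold from synthetic daily samples
syn <- synthesize_observations(cfg, c("Dv:lactate_fermentation" = -25),
                               variables = c("lactate", "acetate", "H2(g)"),
                               sigma = 0.05, seed = 1)
fit <- hierarchical_calibrate(cfg, syn$observations,
                              "Dv:lactate_fermentation", seed = 1)
tidy(fit)
autoplot(sweep_dgmin("Dv:lactate_fermentation", seq(-40, -15, 5),
                     cfg, syn$observations))
```
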