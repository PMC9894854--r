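---
title: "Methods: salp-bloom carbon export budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salp-bloom carbon export budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salpflux)
```

# Scope and model

`salpflux` assembles a per-cycle carbon budget for Lagrangian process
studies in which salp (*Salpa thompsoni*) blooms modulate the biological
carbon pump. Each cycle combines five independent measurement streams:

1. **Demography.** Double-oblique net tows record every individual's
   species, life stage (oozooid = solitary, blastozooid = aggregate) and
   oral-to-atrial length (OAL). Counts are binned into half-open 5-mm bins
   spanning 1–136 mm and scaled areally as
   `ind m^-2 = count / volume * tow_depth`. Day and night tow groups are
   averaged first within, then across, periods with equal weight — the
   usual treatment when vertical migration makes one period
   unrepresentative. Biomass uses a length–carbon allometry
   `C(µg) = a_w L^{b_w}` on bin midpoints; the coefficients are mandatory
   configuration because they are region- and stage-specific (a generic
   literature-style default of `a_w = 0.006, b_w = 2.58` is used in the
   worked examples; substitute the allometry appropriate to your study).

2. **Grazing and egestion.** Gut pigment (chl *a* + phaeopigment,
   `Gpig`, ng ind^-1^) scales with length as `Gpig = a L^b`, fit by
   log-log least squares per cycle; with fewer than three distinct lengths
   the fit falls back to the mean, flagged. Gut passage time is
   `GPT(h) = 2.607 ln(OAL) − 2.6`, divided by a Q10 = 2 factor so warming
   shortens gut residence; the formula is only valid above
   `OAL ≈ 2.71 mm`, and smaller bins contribute zero grazing (logged).
   Hourly grazing is `Gpig/GPT`; daily areal rates weight day and night
   abundances by a 14 h/10 h photoperiod. Carbon units apply a
   configurable C:chl ratio (default 50 g:g) to the chl-equivalent
   pigment; no pigment-destruction correction is applied (the destruction
   factor is exposed as `chl_frac` and defaults to 1). Egestion is
   computed two ways: the pigment route multiplies carbon grazing by an
   egestion efficiency of 0.36, and the length-based route uses
   `Fprod = 0.5388 e^{−0.0212 size}` pellets h^-1^ with
   `OrgC = 0.055 size^{2.0665}` µg C per pellet, Q10-scaled up from its
   0 °C cold-water reference. The two deliberately disagree in general —
   they bracket the egestion term.

3. **Trap fluxes.** Particle-interceptor traps (7 cm inner diameter)
   give `flux = POC / (n_tubes · π (d/2)^2 · duration)`. Depth attenuation
   is fit as `Flux(z) = F0 (z/z0)^{−b}` by unweighted log-space least
   squares with `z0` the euphotic depth; an exponential alternative is
   available to gauge sensitivity to the functional form (on noiseless
   power-law fluxes at 70–300 m it shifts interpolated flux at
   `z0 + 100 m` by ≈ 8%, regression-tested). Intact salp pellets are
   converted from morphometrics through a cylinder volume rule
   `V = π (w/2)^2 L` (ellipsoid optional) and the volume–carbon allometry
   `C = 10^{0.634 log10 V + 1.43}` µg. Pellet fractions above 1 are
   reported with a warning rather than truncated.

4. **Thorium export.** `²³⁴Th` (λ = ln 2 / 24.1 d^-1^) is compared with
   salinity-derived `²³⁸U` (`A_U = 0.0786 S − 0.315`, configurable). The
   steady-state flux integrates the deficiency from the surface
   (shallowest sample continued to 0 m) to the integration depth by the
   trapezoid rule; the non-steady-state variant subtracts the inventory
   change rate between two occupations, interpolated onto a union grid.
   The optional mixing term `−κ ∂²A/∂z²` uses central differences on the
   raw sample grid (so the surface extension cannot inject curvature);
   κ defaults to 0. Uncertainties propagate in quadrature through the
   quadrature weights. Conversion to carbon uses a measured C:²³⁴Th ratio
   (µmol C dpm^-1^; × 12.011/1000 to mg C).

5. **Plankton rates.** The two-treatment dilution design gives
   `g = (k_A − k_B)/(1 − x)`, `µ_n = k_B + g`, `µ_0 = k_C + g` from
   apparent rates `k = ln(final/initial)/t`; negative `g` is floored at 0
   with a flag (conventional practice). Photoacclimation `Φ` is the
   biomass-weighted FL3:FSC rate over picoeukaryote and nanoeukaryote
   populations, computed and subtracted per depth. NPP profiles integrate
   trapezoidally over the euphotic zone with constant end extension.

The pump metrics are `Ez = flux(z_eu)/NPP`,
`T100 = Flux(z_eu + 100)/Flux(z_eu)` on the fitted attenuation curve, and
their product, the fraction of production delivered 100 m below the
euphotic zone. Salp : non-salp comparisons interpolate flux profiles
geometrically (log flux vs log depth, consistent with the power law).

# The synthetic generator

Real deployments of this design deposit their data in public archives
rather than print them, so the package ships a generator whose defaults
*are* the study conditions of a bloom cycle in subtropical frontal
waters: 5 days, 12 °C, euphotic depth 70 m, traps at 70/100/300/500 m,
one day and one night tow per day to 200 m, blastozooid/oozooid
abundances of 64/3 ind m^-2^ with truncated-normal OAL distributions
(30 ± 10 and 70 ± 25 mm), `F0 = 210 mg C m^-2^ d^-1` with `b = 0.39`,
euphotic NPP ≈ 452 mg C m^-2^ d^-1, `µ = 0.6` and `g = 0.4 d^-1`, and a
steady-state `²³⁴Th` export of 1500 dpm m^-2^ d^-1 (kept independent of
the trap flux, as the two are independent measurements in the field).

Noise models are minimal and conventional: Poisson tow counts, lognormal
σ = 0.2 on gut pigments and on *per-tube* trap POC (tubes pooled by
mass, so the pooled flux noise scales as σ/√n_tubes), Gaussian
0.05 dpm L^-1^ on activities, lognormal σ = 0.05 on final bottle chl.
`noise_off()` zeroes all of them and switches counts to rounded
expectations. Expected pellet counts derive from a ground-truth pellet
fraction of flux (default 0.3) so pellet carbon stays physically
consistent with bulk POC at every depth.

The thorium profiles are constructed so the deficiency is constant over
the euphotic zone, tapers linearly to zero 30 m below it, and places a
sample node at the euphotic depth — hence the steady-state estimator
recovers the true export exactly on the default grid, and within
discretisation error on others.

What the generator does **not** emulate: tow-to-tow variance beyond
Poisson (the field data's variance components are unknown), vertical
structure in salp abundance, pigment destruction in guts, swimmer
contamination in traps, non-steady thorium dynamics (the truth is steady
state; the NSS estimator is exercised against a separately
forward-simulated 1D balance in the tests), and nutrient limitation
(the amendment boost is a constant 0.1 d^-1^). Passing recovery tests
therefore demonstrate correctness of the estimators under these stated
conditions, not robustness to every field pathology.

# Numerical and design choices

* **Areal scaling** of a 0–200 m double-oblique tow is concentration ×
  tow depth; day/night means are unweighted by volume (volume already
  divides out per tow).
* **Bin membership** is half-open `[lo, hi)`; out-of-range lengths go to
  the nearest edge bin with a message; bin midpoints carry all
  size-dependent rates.
* **GPT reference temperature** defaults to the study's ambient (scaling
  factor 1) because the relation's native temperature is not published;
  the length-based pellet model's reference is 0 °C (its Antarctic
  source), both configurable via `q10_config()`.
* **λ(²³⁴Th)** uses the physical 24.1-d half-life.
* **Integration** is trapezoidal throughout (`pracma::trapz`), with
  constant continuation at the surface; on smooth profiles the error is
  second order in grid spacing (tested).
* **Ez** uses the trap sitting at the euphotic depth when one exists,
  otherwise the power-law interpolation.
* **Degenerate inputs**: all-zero pigments error; < 3 distinct lengths
  fall back to a mean; a cycle with no salps at all yields zero grazing
  and egestion rather than an error; < 2 positive fluxes refuse an
  attenuation fit; reversed thorium occupation dates error.
* **Problem sizes** in the shipped tests and examples: 10 tows (~1000
  individuals), 4 trap depths × 3 tubes, 9-depth thorium profiles ×2,
  6 dilution depths, and 200-seed noise ensembles — sizes a single cycle
  of the emulated design actually produces.

# Known limitations

Microzooplankton grazing enters the carbon balance as `(g/µ) × NPP`, a
standard but crude conversion; mesozooplankton grazing is an external
input. The non-steady-state thorium estimator is sensitive to activity
noise when the inventory change is small relative to measurement error —
its uncertainty output should be respected. Printed-value metrics
(`ez_ratio` on site-level fluxes and NPP) carry the full uncertainty of
their inputs, which the package does not model at that level. No
hypothesis testing across cycles is provided.
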