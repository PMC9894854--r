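# salpflux

Carbon-export budgets for Lagrangian ocean process studies with salp
blooms.

Salps (*Salpa thompsoni* in the Southern Ocean) are gelatinous filter
feeders whose blooms repackage primary production into large,
fast-sinking fecal pellets. Quantifying how much they strengthen the
biological carbon pump requires combining, per multi-day water-parcel
occupation ("cycle"): size-structured salp abundance from net tows,
grazing from gut pigments, pellet egestion, sinking-particle fluxes from
drifting sediment traps, ²³⁸U:²³⁴Th disequilibrium export, and
phytoplankton growth/microzooplankton grazing from dilution experiments.
`salpflux` implements each stage and assembles them into the pump
metrics used to compare bloom and non-bloom sites:

* **Ez** = POC flux at the euphotic-zone base / integrated NPP,
* **T100** = Flux(z_eu + 100 m) / Flux(z_eu) on a fitted power law
  `Flux(z) = F0 (z/z0)^(-b)`,
* **BCP efficiency** = Ez × T100.

Core rate models: gut passage time `GPT(h) = 2.607 ln(OAL) − 2.6`
(Q10 = 2); grazing `G = Gpig/GPT` with a fitted allometry
`Gpig = a L^b`; egestion both as `0.36 ×` carbon grazing and from
`Fprod = 0.5388 e^(−0.0212 L)` pellets h⁻¹ with
`OrgC = 0.055 L^2.0665` µg; pellet carbon from volume as
`C = 10^(0.634 log10 V + 1.43)` µg; steady- and non-steady-state
1-D ²³⁴Th balances with optional mixing correction; two-treatment
dilution algebra `g = (k_A − k_B)/(1 − x)` with FL3:FSC
photoacclimation correction.

Because studies of this design archive rather than print their raw
data, the package includes a synthetic cycle generator
(`generate_cycle()`) whose defaults are realistic bloom conditions and
whose ground truth is recorded, so the entire pipeline is testable for
parameter recovery.

## Worked example

```r
library(salpflux)

# printed site-level inputs: euphotic-zone flux over integrated NPP
round(ez_ratio(210, 452), 2)   # salp subtropical site     -> 0.46
round(ez_ratio(25, 233), 2)    # non-salp subantarctic site -> 0.11

# a full synthetic bloom cycle, then the whole budget
cyc <- generate_cycle(cycle_scenario(), seed = 1)
res <- run_pipeline(pipeline_config(cycle = cyc))
res
```

```
Cycle budget 'SYN-1'
  NPP (euphotic):           449.0 mg C m-2 d-1
  POC flux at z_eu:         200.6 mg C m-2 d-1 (F0 = 202.2, b = 0.308)
  Ez = 0.447, T100 = 0.761, BCP efficiency = 0.340
  Grazing (uzoo/meso/salp): 302.8 / 0.0 / 4.7 mg C m-2 d-1
  Egestion (Gpig/length-based): 1.7 / 68.4 mg C m-2 d-1
```

The generating truth for this cycle was `F0 = 210 mg C m⁻² d⁻¹`,
`b = 0.39` and NPP ≈ 455 mg C m⁻² d⁻¹: the noisy single-cycle estimates
above recover them within the sampling error the default noise model
implies (and exactly when the scenario uses `noise_off()`). The two
egestion estimates deliberately bracket the pellet-production term; the
length-based method runs higher because its cold-water rates are
Q10-scaled up to ambient temperature.

## Analysis workflow

`analysis/` holds numbered drivers that narrate a two-cycle contrast
(bloom vs no-bloom) end to end, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # generate both cycles' field tables
Rscript analysis/02_salp_population.R # binned abundance and biomass
Rscript analysis/03_grazing_egestion.R
Rscript analysis/04_export_flux.R     # traps + thorium
Rscript analysis/05_plankton_rates.R  # dilution + NPP balance
Rscript analysis/06_bcp_budget.R      # pump metrics, salp:non-salp ratios
```

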