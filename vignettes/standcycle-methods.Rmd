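---
title: "standcycle: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{standcycle: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standcycle)
```

## What the package models

`standcycle` is a reduced-complexity annual carbon-pool model for
landscapes shaped by stand-replacing wildfire and wood harvest, together
with the analysis machinery used to evaluate and attribute such a model:
factual/counterfactual site evaluation, factorial flux attribution, and
rolling-trend / source–sink diagnostics. It deliberately omits the physics
a full land-surface scheme would carry — energy and water balance,
phenology, sub-annual photosynthesis, nitrogen, peatlands, permafrost,
dynamic vegetation — so that the disturbance–recovery carbon accounting
itself is small enough to audit line by line. Every operator conserves
carbon exactly, and the simulator verifies each cell-year that the pool
change equals net biome productivity (NBP).

## The annual pool model

Each tile (age cohort) carries eight pools: green leaf, brown leaf, stem,
root, litter, soil, and short- and long-lived harvested-wood products.
The annual update is:

1. **GPP** `= gpp_max · vcmax_scale · f_age · f_T · f_CO2`, with
   `f_age = 1 − exp(−age/τ_rec)`, `f_T = exp(β_gpp ΔT)` and
   `f_CO2 = max(0, 1 + γ ln(c/c₀))`.
2. **Autotrophic respiration**: maintenance proportional to live pool
   masses with a Q10 temperature response, plus growth respiration as a
   fraction (0.25) of the post-maintenance assimilate; all respiration
   rates carry the global `respiration_scale`.
3. **Allocation** of NPP to leaf/stem/root by fixed fractions. When NPP is
   negative (a freshly disturbed tile respiring more than it fixes), the
   deficit is drawn from the live pools in proportion to their mass, so no
   pool can be driven negative by allocation into an empty compartment.
4. **Turnover**: green leaf → brown leaf → litter; stem and root → litter
   (forward-Euler annual rates, all ≤ 1 yr⁻¹).
5. **Decomposition**: litter decays with a humified fraction (0.30)
   transferred to soil and the rest respired; soil decays to the
   atmosphere. Both use the same Q10 and `respiration_scale`.
6. **Products** decay with the exact exponential discretization
   `emission = pool·(1 − e^(−k))`, so a rate of `ln 2` gives a one-year
   half-life. The other pools use forward Euler; at the default rates the
   discretization error is far below the closure tolerances and the exact
   form for products keeps the product half-life interpretable.

The ledger identities `ER = Ra + Rh`, `NEP = GPP − ER` and
`NBP = NEP − fire CO2 − product emission` hold to 1e-12 relative; harvest
removals are internal transfers (they reach the atmosphere only through
product decay), so total carbon change per year equals NBP exactly.

## Parameters and why

| parameter | default | rationale |
|---|---|---|
| `vcmax_scale` | 1.11 | carboxylation capacity raised 11%, part of the headline calibration |
| `respiration_scale` | 0.75 | all basal/maintenance/growth respiration reduced 25% |
| `gamma` | 0.5 | halves the unmodified logarithmic CO2 response; within observational uncertainty of seedling downregulation experiments |
| `c0` | spin-up-year CO2 | CO2 is held at this value during spin-up; the fertilization response is referenced to it |
| `gpp_max` | 0.9 kg C m⁻² yr⁻¹ | mature boreal-conifer GPP of order 1 kg C m⁻² yr⁻¹ after the vcmax scaling |
| `tau_rec` | 18 yr | puts the GPP/AGB plateau ≈ 50 yr after disturbance, the observed chronosequence timescale |
| `beta_gpp`, `q10` | 0.02 °C⁻¹, 2.0 | warming raises respiration faster than uptake, so the climate channel of the attribution is a net source |
| allocation | 0.30/0.45/0.25 | leaf/stem/root split typical of conifer stands; stem-heavy so AGB dominates biomass |
| `tau_stem` | 20 yr | stem pool equilibrates on the same ~50-yr horizon as the age response |
| litter/soil rates | 0.15, 0.02 yr⁻¹ | litter turnover of years, soil of decades; equilibrium soil ≈ 12 kg C m⁻², total ≈ 25 kg C m⁻² |

The fire partitioning table (green leaf 0.67/0.32 woody and 0.82/0.17
nonwoody to CO2/litter, brown leaf 0.90/0.09, stem 0.165/0.83 needleleaf
and 0.125/0.87 broadleaf) encodes stand-replacing combustion; the small
residual of each live tissue (e.g. 1% of green leaf) is retained as live
carbon on the new age-0 tile, standing in for surviving structure and
standing dead wood. Three disturbance parameters have no published values
and are package choices exposed as configuration: root fire fate (0%
combusted, all killed roots to litter — belowground tissue rarely burns),
litter/soil combustion fractions (0.10/0.02), and the harvest partition
(85% of stem to products split 0.4/0.6 between 5-yr and 50-yr pools,
residues to litter).

## Tiling

Disturbance splits the disturbed area off into a single new age-0 tile per
year; the area is drawn proportionally from all tiles by default (an
oldest-first rule is available) because no sub-cell spatial information
exists. When the count exceeds 12, the two tiles closest in age merge
(ties: smallest combined area), with area-weighted pools and age — nearest
-age merging preserves the age structure that drives recovery fluxes,
which is the quantity the analysis cares about. Annual burned area can be
disaggregated to months with a fire-season climatology
(`disaggregate_burn`); this is reporting-only, as all pools are annual.

## Protocols

Site runs spin up to equilibrium holding CO2 at the 1700 value, loop the
earliest 25 years of climate until 1900 (with transient CO2), then run
fully transient; no tiling is used, and a single 100% disturbance resets
the stand through the same split/partition code path. Domain runs use the
same structure anchored at 1750 with dynamic tiling. Spin-up iterates
25-year climate cycles until total carbon changes by less than 1e-4
kg C m⁻² per cycle (cap 400 cycles; failure names the slowest pool). The
spin-up state depends only on parameters and the looped climate, so one
spin-up is shared across all factorial and scenario runs of a cell.

## The synthetic study conditions

The generators define the study conditions and are not tuned per analysis:

- **Climate/CO2** (`gen_forcing`): AR(1) interannual temperature anomalies
  (φ = 0.6, sd 0.5 °C) with 2 °C/century warming from 1970; CO2 ramps
  289→420 ppm over 1900–2023 (quadratic in time, flat before 1900).
- **Disturbance ensemble** (`gen_scenarios`): a 2×2 design. All members
  share one right-skewed lognormal burned-fraction realization (mean
  0.004 yr⁻¹) and one harvest realization (clipped normal, mean
  0.002 yr⁻¹). "Inferred" members add 0.008 before 1918; "vector" members
  add 0.00175 from 1985. On the nominal 400 Mha domain these correspond to
  a ~1.6 Mha yr⁻¹ baseline, a 3.2 Mha yr⁻¹ pre-1918 increment and a
  0.7 Mha yr⁻¹ record-type increment, i.e. the pre-observational era is
  where the scenarios genuinely disagree.
- **Pseudo-towers** (`gen_tower_obs`): iid Gaussian observation noise on
  the factual run's fluxes and biomass.

Real burned-area fields are spatially and temporally autocorrelated,
scenario differences are not literally additive constants, and tower error
is neither iid nor Gaussian; passing tests therefore demonstrate that the
analysis chain is correct and well-conditioned under these idealized
conditions, not that the model reproduces any particular national carbon
budget. Desk-scale problem sizes (6 cells × 274 yr for the ensemble, 14
sites for the twin experiment, 1000-replicate trend calibrations) keep the
full suite and acceptance run in minutes while leaving all rates and
tolerances at their scientific values.

## Attribution bookkeeping

Factorial runs hold one driver at its spin-up state (climate looped, CO2
at c₀, disturbance zeroed, or zeroed before a boundary year). Over an
averaging window, the climate and CO2 channels are window means of
`NBP_ALL − NBP_factor-fixed`. The disturbance effect is split into
immediate emissions (fire CO2 + product decay, read from the ALL ledger),
the decomposition legacy (−ΔRh between ALL and no-disturbance), and
recovery (Δ(GPP − Ra)). With this model's flux definitions these three sum
to `NBP_ALL − NBP_no-disturbance` identically, so the closure residual is
a float-level audit — it is computed and reported rather than assumed. In
this reduced model the continuously disturbed landscape carries *less*
litter and soil than its counterfactual (fire exports dead carbon), so the
decomposition channel is a relative sink and the recovery channel (younger,
lower-GPP stands) a relative source; the net disturbance effect is still a
source, and the ensemble bracket structure — wide where the scenarios
disagree about the pre-1918 era, narrow in the observation era — is the
quantity of interest.

## Numerical and design decisions

- Years are integers; no calendar or leap-year logic.
- `co2_response` is isolated behind one function so the logarithmic
  downregulation form can be swapped; the log form is the simplest with a
  single unitless γ.
- GPP is driven by stand age, not leaf area, so regrowth restarts from the
  age signal even when 100% harvest removes all live mass.
- Negative pools after an update raise an error; only float dust below
  1e-12 is zeroed.
- Trend tests are plain OLS with two-sided t p-values; no autocorrelation
  correction and no multiple-testing correction across windows (raw
  per-window p-values are reported). Constant windows get slope 0, p = 1.
- Running means place their value at the mean year of their window, which
  keeps the zero crossing of a linear series exact; the source–sink
  crossing extrapolates an OLS fit to the last 15 smoothed values and
  reports non-crossing members separately (ensemble spread across the four
  scenarios is the uncertainty measure).
- Multi-disturbance sites anchor years-since-disturbance at the most
  recent event.
- The package has no command-line binary: the exported functions and the
  acceptance script are the interface.

## Known limitations

No spatial autocorrelation in the generators; iid cells. One PFT per run
(the class only switches fire partition fractions). The decomposition/
recovery split of the disturbance channel is one defensible bookkeeping
among several; it is documented above and closure-audited, but other
models split differently. Absolute national magnitudes depend on the
nominal domain area and are not comparable to full-model, real-forcing
estimates — only the structure (signs, closure, bracket ordering,
recovery timescales) is.
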