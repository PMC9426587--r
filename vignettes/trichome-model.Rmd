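---
title: "A coarse-grained diel model of Trichodesmium physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained diel model of Trichodesmium physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichodiel)
```

## The problem

*Trichodesmium* is a filamentous marine cyanobacterium that fixes N~2~ while
running O~2~-evolving photosynthesis in the same daylight hours, although
nitrogenase is destroyed by O~2~. `trichodiel` simulates one trichome over a
12-h light period as a small set of coarse-grained pools — carbohydrate
(CH~2~O), carbon skeletons (CS), fixed nitrogen (N) and intracellular O~2~ —
coupled through an instantaneous ATP/NADPH economy, and asks under which
conditions a *unified* trichome (every cell photosynthesizes and fixes N~2~)
can grow as well as one that confines N~2~ fixation to specialized
*diazocytes* (the spatially *segregated* variant).

## Model structure

### Light and electron transport

Irradiance is a half-sine over the light period `T_light` = 12 h with peak
`I_max`. It drives photosynthetic electron transport (PET) with a saturating
light response and a feedback inhibition by respiratory protection (RP):

$$V_{PET} = v_{PET}^{max}\,(1 - e^{-\alpha_I I})\; e^{-\beta V_{RP}}.$$

Electrons split between the linear pathway (LPET: 0.65 ATP, 0.5 NADPH,
0.25 O~2~ per electron) and an alternative Mehler-type pathway (AET: 0.65 ATP,
no net NADPH or O~2~). The AET fraction $f_{AET}$ is the model's valve for
matching the ATP:NADPH supply ratio (1.3 at pure LPET, rising with $f_{AET}$)
to instantaneous demand.

### Energy allocation

ATP and NADPH are not storable, so at each instant `allocate_energy()` solves
a two-currency balance with N~2~-fixation priority: N~2~ fixation (9 ATP,
3 NADPH per N) is capped by the ATP budget including a 10% maintenance
surcharge; carbon fixation (3 ATP + 0.8 ATP of CCM cost, 2 NADPH per C) takes
the entire ATP residual; $f_{AET}$ is then set so NADPH supply equals NADPH
demand exactly. Both currencies therefore close identically at every accepted
time step, which the test suite asserts on every output grid point.

A deliberate design choice sits here. The textbook "required AET fractions"
(56.7% for the 3:1 ratio of N~2~ fixation, 31.6% for the 1.9:1 ratio of
carbon fixation; `required_aet_fraction()`) are derived from the *bare
process* stoichiometries. Inside the simulator the maintenance surcharge
rides on the ATP side, so the realized endpoints are
$1 - 1.3/(1.1\cdot3) = 60.6\%$ and $1 - 1.3/(1.1\cdot1.9) = 37.8\%$. We chose
exact two-currency closure (with the surcharge) over matching the bare
endpoints because the published daily diagnostics are mutually consistent
only that way: with daily ATP demands of roughly $3.8\,C + 9\,N$ plus 10%
maintenance and the nighttime biosynthesis respiration, a daily AET electron
fraction of ~39% and an ATP share of ~81% to carbon fixation both drop out of
the same arithmetic; excluding maintenance from the split yields ~33% and
~89% instead.

### Metabolic rates

N~2~ fixation runs below an energetic ceiling (`nf_max()`, all PET energy to
N~2~ fixation at its required AET fraction) under three Michaelis-type
regulators: carbon-skeleton availability, filling of N storage, and O~2~
inhibition with half-saturation `kO2NF`. Carbon-skeleton synthesis
(`cs_rate()`) converts carbohydrate without energy cost and self-inhibits as
`CS_max` fills; skeletons are not consumed during the day — they act as the
demand signal for N~2~ fixation and are folded into biomass at night.
Respiratory protection (`rp_rate()`) burns carbohydrate at 1 O~2~ per C (the
1:1 carbohydrate-combustion stoichiometry, our choice where the literature
is silent) in
proportion to intracellular O~2~, light and the same N~2~-fixation demand
signals, and its ATP is discarded.

### Oxygen

O~2~ exchanges across the cell envelope by a radial series-resistance scheme
for a cylinder: membrane (diffusivity $\varepsilon\, d_{O_2}$, with
$\varepsilon \approx 10^{-4}$) plus a diffusive boundary layer of thickness
$L_b = 1024\,(R + L_g)$. The printed multiplier 1024 looks suspicious at
first sight, but it survives a consistency check: with it, dropping
$\varepsilon$ to $10^{-5}$ makes the model's morning O~2~ peak ~61x the
ambient concentration, matching the reported "about 60 times" for that
experiment, so we keep it (it remains configurable via `k_b`). In the
segregated variant each cell type talks through its membrane to a common
quasi-steady mixed layer (no storage; its concentration is the
conductance-weighted mean), which drains through the boundary layer. The
volume-weighted cell fluxes then equal the net trichome-environment flux
exactly, and total O~2~ is conserved by construction.

### The diel cycle and growth

State variables integrate over the light period from empty pools and ambient
O~2~ (yesterday's pools went into biomass) with a stiff-capable solver
(`deSolve::lsoda`; the O~2~ equation relaxes on ~1 s against a 43200-s day).
At dusk, biomass is synthesized in a single algebraic solve: part of the
carbohydrate is respired (5 ATP per C) to pay the biosynthesis cost (2 ATP
per C, plus 10% maintenance), the rest plus all skeletons become biomass,
and the realized biomass is the smaller of this C-based value and the
N-based value $N/0.159$. Growth is $G = \ln(1 + Bio)$ per day.

### Spatial segregation and transfer losses

In the segregated variant diazocytes make up `f_D` = 15% of cells, have no
PET, and host all N~2~ fixation (per-diazocyte biomass, sensing diazocyte
O~2~); photosynthetic cells host PET, carbon fixation and most RP. Pools are
communal. A transfer-loss experiment charges a fraction $\lambda$ of every
material that must physically change cell type: ATP, NADPH and carbohydrate
demanded by diazocytes are drawn at demand$/(1-\lambda)$, and only
$f_D + (1-f_D)(1-\lambda)$ of fixed N is credited to the communal pool (the
share diazocytes keep for themselves is loss-free). At $f_D \to 0$ (with
N~2~ fixation falling back to the photosynthetic cells) and $\lambda = 0$
the variant reduces to the unified model, which is regression-tested.

## Parameters

Two tiers of parameters exist.

**Published constants** (stoichiometries, `QC` = 18333 mol C m^-3^,
`O2_far` = 0.213 mol m^-3^, `kO2NF` = 10^-2^ mol m^-3^,
$\varepsilon = 10^{-4}$, `f_D` = 0.15) and the four **optimizable
parameters** with their published optima (`kCSNF` = 0.06,
`vCS_max` = 3.7e-6 s^-1^, `kCH2O_CS` = 0.58, `vRP_max` = 4.5e-4 s^-1^
unified / 4.0e-4 segregated) are taken as printed.

**Constants deferred to supplementary material** we could not obtain
verbatim. We fixed the physics at standard magnitudes — O~2~ diffusivity in
seawater $d_{O_2} = 2.1\times10^{-9}$ m^2^ s^-1^ at 25 °C, membrane
thickness $L_g = 50$ nm, trichome length $L = 0.5$ mm (~100 cells),
mixed-layer thickness $L_m = 1\,\mu$m, noon irradiance
`I_max` = 2000 µmol photons m^-2^ s^-1^ — and pinned
`vPET_max` = 2.0e-3 mol e^-^ (mol C)^-1^ s^-1^ from the published search
bound for the maximal rates (5.0e-4 is described as the maximal potential
PSII O~2~ production, which is 0.25 `vPET_max`). The remaining five —
$\alpha_I$, $\beta$, `N_max`, `CS_max` and the cytoplasm radius `R` (cell
width varies ~6-22 µm across *Trichodesmium* species, and with it the
membrane O~2~ conductance that prices the low-O~2~ window) — were set once
by `calibrate_unknowns()` (`analysis/00_calibrate.R`): a bounded
Levenberg-Marquardt match, jointly over both model variants at their
published free-parameter optima, to the published daily outcomes
(unified: gross C = 2.24, gross N = 2.24/49, daily AET fraction 39%,
$G = 0.25$ day^-1^; segregated: 2.21, 0.11, $G = 0.51$). The fit converges
with every residual under 2% at $\alpha_I = 4.63\times10^{-4}$,
$\beta = 1.87\times10^{4}$, `N_max` = 0.165, `CS_max` = 7.76 and
$R = 7.2\,\mu$m (trichome width ~14 µm). `CS_max` lands far above the
carbon-skeleton levels the model ever reaches (< 0.2), i.e. the calibration
effectively switches the skeleton self-inhibition off. The calibrated
values shipped as defaults are therefore *model-derived, not canonical*;
every quantity downstream of them (the headline daily rates, budget fractions,
ablation deltas) inherits calibration error, and the calibration report
states the tolerances under which such quantities are compared: calibration
targets ±2%, emergent quantities ±20% (or 5 percentage points on a
fraction, whichever is looser).

Two published experiment outcomes remain outside those bands under the
calibrated constants and are knowingly left failing in the acceptance
tests: the growth collapse from ablating AET (we find −89% vs the published
−62%; the O~2~-production and RP responses do agree) and the gross C:N of
the weak-O~2~-inhibition endpoint (kO2NF = 0.1: we find ~34 vs the
published 23, while its re-optimized growth rate does agree). Both involve
the fragility of the low-O~2~ window, which depends on constants we could
only calibrate, not copy.

## Numerical choices

* Solver: `lsoda`, `rtol` = 1e-7, `atol` = 1e-10; tightening both by 10x
  changes $G$ by well under 0.1% (asserted in tests).
* Output and integration grid: 60-s spacing; daily integrals by trapezoid on
  that grid.
* Pool exhaustion: consumption of CH~2~O (RP, skeleton synthesis) is scaled
  by a limiter that is exactly 1 above 10^-6^ mol (mol C)^-1^ and ramps
  linearly to 0 at an empty pool — a pure numerical guard that never engages
  in healthy runs.
* Degenerate instants (dawn/dusk, `V_PET` = 0) return all-zero allocations
  with a `light_limited` flag rather than errors; `f_AET` is clipped to
  [0, 1] because transient demand ratios below 1.3 are legitimate.
* The daily AET fraction is reported electron-weighted,
  $\int f_{AET} V_{PET} \mathrm{d}t / \int V_{PET} \mathrm{d}t$, since the
  published figure is a fraction of PET electrons.
* Optimizer: Latin-hypercube starts over the published bounds, `L-BFGS-B` on
  parameters rescaled to [0, 1] (the rate constants span orders of
  magnitude); deterministic for a given seed; all starts are returned.
  Defaults (`n_starts` = 64) are a desk-scale compromise; tests and the
  example analyses use smaller counts with coarser solver settings because
  they exercise machinery, not accuracy.

## A worked run

```{r run, eval = FALSE}
r <- integrate_diel(fixed_parameters(),
                    default_optimized_parameters("unified"),
                    run_config())
r
daily_budgets(r)
```

The printed summary reports the daily growth rate, gross C and N~2~ fixation
and their ratio, and the daily AET fraction; `daily_budgets()` partitions
gross carbon, ATP (daytime PET plus nighttime respiration), NADPH and O~2~
into closed fraction sets. The `analysis/` scripts run the full experiment
suite (segregation comparison, transfer-loss sweep, kO2NF x epsilon
sensitivity, vCS_max sweep, AET/RP ablations, optimization) and write tidy
CSV/JSON under `results/`.

## What the model does and does not claim

The simulator emulates the *in-silico* physiology of a single suspended
trichome: smooth sinusoidal light, constant far-field O~2~, one diel cycle
with an end-of-day biosynthesis step, no nutrient limitation other than
fixed N, no colonies, particles, attached heterotrophs, hopanoid membrane
dynamics, photoinhibition or multi-day acclimation. Passing tests therefore
show internal consistency (conservation, closure, reproducibility) and
agreement with the published *model* behaviour under calibrated constants —
not agreement with field or culture observations. Because five constants are
calibrated against the headline daily rates of the two variants, those rates
are fitted, not predicted; the genuinely emergent checks are the budget
fractions, the transfer-loss crossover, the sensitivity endpoints, the
ablation responses and the near-recovery of the published free-parameter
optima by the growth maximizer, all computed with no further freedom.
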