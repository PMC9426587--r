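# trichodiel

A coarse-grained diel physiology model of a *Trichodesmium* trichome.

*Trichodesmium* is a filamentous marine cyanobacterium that fixes N₂ in full
daylight even though its photosynthesis evolves O₂ and nitrogenase is
O₂-sensitive. `trichodiel` simulates one trichome over a 12-h light period —
pools of carbohydrate (CH₂O), carbon skeletons (CS), fixed N and
intracellular O₂, coupled through an instantaneous ATP/NADPH economy — to
test whether a *unified* trichome (all cells do everything) can sustain
N₂ fixation by temporal segregation alone, or whether confining N₂ fixation
to specialized diazocytes (*spatial* segregation) is required. The package is
aimed at researchers in marine microbial ecology and metabolic modelling.

## Model core

Photosynthetic electron transport responds to light and is inhibited by
respiratory protection (RP):

    V_PET = vPET_max · (1 − e^(−αI·I)) · e^(−β·V_RP),    I(t) = I_max · sin(πt/T)

Electrons split between linear transport (LPET: 0.65 ATP, 0.5 NADPH, 0.25 O₂
per e⁻) and a Mehler-type alternative (AET: 0.65 ATP only). The AET fraction
f_AET is set at every instant so that the ATP:NADPH supply ratio matches
demand exactly; N₂ fixation (9 ATP, 3 NADPH per N) has priority and carbon
fixation (3 + 0.8 ATP of CCM cost, 2 NADPH per C) takes the ATP residual,
with a 10% maintenance surcharge on all process ATP. N₂ fixation is further
throttled by carbon-skeleton supply, N-storage filling and Michaelis-Menten
O₂ inhibition (half-saturation kO2NF = 10⁻² mol m⁻³); RP burns carbohydrate
(1 O₂ per C, ATP discarded) to hold intracellular O₂ down; O₂ exchanges with
the environment through a cylindrical membrane/boundary-layer resistance
(membrane diffusivity ε·d_O2, ε = 10⁻⁴). At dusk a single algebraic solve
respires part of the carbohydrate (5 ATP per C) to pay biosynthesis (2 ATP
per C), giving biomass Bio = min(Bio_C, N/0.159) and growth
G = ln(1 + Bio) per day.

Four kinetic parameters (kCSNF, vCS_max, kCH2O_CS, vRP_max) are
growth-optimized quantities with published optima, shipped as
`default_optimized_parameters()`; a multistart optimizer
(`optimize_growth()`) can re-derive them. Constants that the primary
literature defers to supplementary material (α_I, β, N_max, CS_max and the
geometry) are set to standard magnitudes or calibrated once against the
published daily outcomes — see the methods vignette
(`vignettes/trichome-model.Rmd`) and `analysis/00_calibrate.R`; they are
model-derived, not canonical.

## A worked example

```r
library(trichodiel)

r <- integrate_diel(fixed_parameters(),
                    default_optimized_parameters("unified"),
                    run_config(variant = "unified"))
r
```

```
Diel trichome simulation (unified variant)
  growth rate G        : 0.252 day-1
  gross C fixation     : 2.262 mol C (mol C)-1 day-1
  gross N2 fixation    : 0.0455 mol N (mol C)-1 day-1
  gross C:N            : 49.7
  daily AET fraction   : 38.8%
```

The trichome fixes ~2.3 mol C per mol cellular C per day, but only ~13% of
it ends up as biomass: ~80% is burned by respiratory protection to keep the
mid-day intracellular O₂ low enough (the "low-O₂ window") for the ~0.046 mol
N (mol C)⁻¹ day⁻¹ of N₂ fixation — a gross C:N fixation ratio near 49.
About 39% of PET electrons take the non-O₂-evolving AET route.
`daily_budgets(r)` decomposes the day into closed carbon, ATP, NADPH and O₂
fraction sets, and `r$series` holds the full time series (state, rates,
energy terms, O₂ fluxes) on a 1-min grid.

The numbered scripts under `analysis/` reproduce the full experiment suite —
unified vs segregated comparison, transfer-loss sweep (the segregation
advantage flips sign when more than ~half of transferred material is lost),
kO2NF × ε sensitivity, vCS_max sweep, AET/RP ablations, optimization — each
writing tidy CSV/JSON under `results/`.

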