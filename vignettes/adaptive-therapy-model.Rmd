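---
title: "A hybrid agent-based model of two-drug adaptive cancer therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid agent-based model of two-drug adaptive cancer therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atsim)
```

## The model

`atsim` simulates a small tumor evolving under two-drug treatment. The tumor
is a set of cells on a 100 x 100 square lattice (one cell per site, so the
carrying capacity is 10,000 cells). Each cell carries one of four heritable
phenotypes: doubly sensitive, resistant to drug 1, resistant to drug 2, or
doubly resistant. Resistance carries a fitness cost expressed through the
division rates, which decrease from sensitive to singly resistant to doubly
resistant.

Each step is one hour. Within a step:

1. **Drug field.** If the hour is a scheduled application, a uniform dose of
   each drug is added to every site (a well-perfused tumor). The two
   concentration fields then diffuse (an alternating direction implicit
   solve of the 2-D diffusion equation, reflecting boundaries) and decay
   exponentially.
2. **Cells.** Every cell present at the start of the hour is visited once,
   in a fresh uniform random order. A visited cell first survives or dies: the
   death probability is `background + S1 [Drug1] psi1 + S2 [Drug2] psi2`,
   where `S_k` is 1 if the cell is sensitive to drug `k` and 0 otherwise,
   `[Drug_k]` is the local concentration and `psi_k` the potency (death
   probability per unit concentration per hour). A survivor divides with its
   phenotype's division probability. The daughter is placed uniformly at
   random among empty Moore-neighborhood sites; if the neighborhood is full,
   the divider replaces a uniformly chosen neighbor with probability `r`
   (the replacement parameter: `r = 0` is contact inhibition, `r = 1`
   neighbor killing). Daughters mutate to each other permitted phenotype
   with probability `mu` per division. Cells born during a step are not
   revisited within it.

Tumors are seeded as a disc (radius 10, 317 cells) at the lattice center
with phenotypes drawn uniformly, and each run lasts 5000 steps (about 208
days). A run "progresses" the first time a 500-step rolling mean of either
the total burden (threshold 98% of capacity) or the doubly resistant count
(20% of capacity) crosses its threshold; runs always continue to the full
horizon so that drug usage is accounted over the same amount of time in
every arm.

## Treatment controllers

Tumor burden is measured every 3 days with Gaussian noise (SD 5 cells,
rounded, floored at zero). The controller sees only these noisy
measurements; true counts are used only for progression scoring. Treatment
starts the first time a measurement reaches 50% of capacity. Decisions are
made at each 3-day measurement; the decided doses are administered once
every 24 h, anchored at the initiation step.

* **ST** — both drugs at the cocktail maximum tolerated dose (3 units each)
  every day, forever.
* **DM Cocktail** — both doses scaled together by `1 + delta_dose` when the
  measured burden grew by more than `delta_tumor` (or exceeded its running
  maximum), by `1 - delta_dose` when it shrank by at least `delta_tumor`,
  unchanged otherwise; clamped to `[0.5, 3]` units.
* **DM Ping-Pong Alternate** — one drug at a time, switching every cycle;
  each drug's dose is adjusted by the response since that drug last began a
  cycle; capped at the single-drug MTD (5 units).
* **DM Ping-Pong on Progression** — stays on the active drug while the
  tumor is stable or shrinking (scaling the dose down on shrinkage) and
  switches drugs on growth, resuming the other drug at its last dose scaled
  up (first use: MTD).
* **FD Dose-Skipping** — a fixed 2.25-unit cocktail (75% of the cocktail
  MTD) applied only in cycles where the tumor grew or exceeded its running
  maximum.
* **FD Intermittent** — the same fixed cocktail with hysteresis on the
  absolute burden: off once the burden has fallen 50% below the initiation
  burden, on again once it regrows to the initiation burden.

DM protocols also take *treatment vacations*: while the measured burden is
at or below 25% of capacity no drug is administered for the cycle. The
modulation bookkeeping (dose memory, ping-pong switching) continues through
a vacation and only administration is suspended; we chose this over freezing
the controller because a frozen memory can never walk the dose down --- every
shrinking cycle coincides with a vacation --- so the controller degenerates
into an all-or-nothing MTD pulser, which contradicts the intent of dose
modulation. The running-maximum override is classified as growth in every
DM protocol (for Ping-Pong on Progression it therefore forces a drug
switch).

## Defaults and units

| Parameter | Default | Units |
|---|---|---|
| division rates (S, R1, R2, R12) | 0.06 / 0.04 / 0.04 / 0.02 | per hour |
| background death rate | 0.01 | per hour |
| replacement probability `r` | 0.5 | — |
| mutation rate `mu` | 1e-3 | per division per target type |
| potencies `psi1`, `psi2` | 0.04 | per unit concentration per hour |
| drug decay | 10% | per hour |
| diffusion coefficient `D` | 2.0 | lattice units^2 per hour |
| MTD | 5 (single) / 3 (cocktail, per drug) | units |
| minimum dose | 0.5 | units |
| `delta_tumor` / `delta_dose` | 10% / 50% | — |
| measurement period / noise | 72 h / 5 cells | |

The default net growth rates are 0.05, 0.03, 0.03 and 0.01 per hour, i.e.
doubling times of 13.9, 23.1, 23.1 and 69.3 hours and a five-fold net-growth
cost for double resistance (1.7-fold for single resistance).
`experiment_presets()` returns the full catalog of study conditions (3x
fitness cost, low/high turnover with doubling times held fixed, tenfold
slowed kinetics, replacement 0/0.5/1, `delta_tumor` and `delta_dose` grids,
vacation thresholds at 10/50/80% of the initiation burden, FD-Intermittent
stop thresholds, and the no-reverse-mutation variant).

## Numerical choices

* The engine's hot loop (the hourly cell sweep and the ADI solver) is
  compiled C++; all randomness flows through R's RNG, so a run is fully
  reproducible from its seed, and replicate `i` of a cohort uses seed
  `base_seed + i - 1`.
* The ADI solve uses zero-flux boundaries (the tumor is seeded centrally
  and the boundary condition is otherwise a free choice) and conserves mass
  to floating-point rounding. The unit-time step is taken as `ceiling(2D)`
  Peaceman-Rachford sub-steps so that sharp sources are resolved
  accurately; with uniform dosing the field is spatially uniform, which is
  an exact fixed point of the operator and is short-circuited.
* Dosing adds to the existing concentration (delivery on top of residual
  drug); with 10%/h decay the steady-state daily-mean concentration is
  0.386 x the daily dose.
* Death probabilities are clamped at 1 as a safety contract; the default
  parameters never reach the clamp.
* `step_world_r()` is a deliberately naive, order-explicit R restatement of
  the step rule, kept as an independent oracle: the test suite checks the
  compiled step against it in distribution on a 3 x 3 lattice.
* A no-reverse mutation variant forbids every resistance-removing
  transition, including swaps between the two singly resistant types (a
  swap loses one resistance).

## What the simulations do and do not show

The model is a caricature of a tumor cross-section: 10^4 sites rather than
10^9 cells, a compensatingly high mutation rate, no vasculature, immune or
stromal compartment, no 3-D architecture, and drug delivery that is uniform
in space. Conclusions about protocol rankings therefore concern the model's
competition dynamics, not any specific cancer.

Within the model, protocol performance is governed by spatial competition:
a densely packed lattice suppresses the doubly resistant clone (crowded
cells rarely place daughters, and faster-dividing neighbors replace them),
while any episode that opens space --- an aggressive dose pulse, a deep
burden crash --- hands the resistant clone free exponential growth at its
intrinsic 0.01/h net rate. In our hands the controllers, run at the stated
measurement cadence and kill rates, hold the tumor porous: the
drug-sensitive matrix is pinned near net-zero growth while the doubly
resistant clone accrues steadily, so every arm progresses within roughly
55--70 days of the resistant takeover clock. Standard treatment fails by
competitive release, dose modulation shifts progression later by a few
days and uses less drug, and because the arms' progression-time
distributions largely overlap, pairwise hazard ratios carry substantial
seed-to-seed variance. The relative benefit of high cell turnover for the
modulated cocktail, the eradication of non-mutating sensitive tumors under
standard treatment, and the drug-usage ordering of the protocols emerge
from the same mechanics. The acceptance script (`scripts/acceptance.R`)
recomputes the headline comparisons from scratch; the test suite asserts
the expected magnitude of each, and blocks the simulation does not
reproduce are left failing rather than relaxed.

## Problem sizes used in the tests

Unit and property tests run on miniature lattices (3 x 3 to 72 x 72) with
shortened horizons; these sizes were chosen so each property is tested at
the smallest scale at which it is meaningful. The cohort comparisons in the
acceptance suite use the full study conditions: 100 x 100 lattice, 5000
steps, 50 replicates per arm.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(protocol = "DM_COCKTAIL", seed = 1)
run <- run_simulation(cfg)
print(run)
plot(run)

st  <- run_replicates(sim_config(protocol = "ST"), n = 10, base_seed = 1)
dmc <- run_replicates(cfg, n = 10, base_seed = 100)
cox_hazard_ratio(rbind(st$survival, dmc$survival), reference = "ST")
drug_usage_fraction(dmc, st)
```
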