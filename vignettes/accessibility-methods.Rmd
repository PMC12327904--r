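---
title: "Methods: simulating geographical accessibility to home medical care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating geographical accessibility to home medical care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homereach)
```

## The problem and the model

Home medical care is delivered at the patient's residence, so the cost of
providing it is borne by the traveling clinician. Geographical
accessibility — how far and how long the closest providing facility must
travel — therefore varies sharply between urban cores and depopulated
mountainous municipalities, and a prefecture planning its service supply
needs to know where that disparity is concentrated and how much of it would
disappear if more facilities provided the service.

`homereach` frames this as a two-scenario closest-facility simulation:

* **Actual scenario** — only facilities observed to provide home medical
  care may serve patients. Providers are identified from claims: a facility
  qualifies if it billed at least one claim carrying one of the eight home
  medical care service codes for a patient aged ≥ 75 in the study fiscal
  year (`identify_providers()`).
* **Ideal scenario** — every hospital and clinic serves patients (dental
  clinics are excluded from the facility registry by construction).

Hypothetical patients stand in for the confidential claims cohort. Each
municipality receives as many patients as it has distinct qualifying
claimants (`usage_summary()`), allocated to 500 m population-mesh cells
proportionally to the cell population aged ≥ 75 and placed uniformly at
random within their cell. For each patient the closest facility is found by
a multi-source Dijkstra query over the road network, and the travel time
and distance *of that same optimal path* are recorded. The whole process is
repeated over `n_trials` (default 10) independent patient draws to absorb
placement uncertainty, and the pooled observations are summarized per
municipality.

Key modeling assumptions, inherited from the study design this package
operationalizes:

* travel is from the *closest* facility, which may lie outside the
  patient's municipality;
* facility capacity is ignored — a known limitation, not an oversight;
* patients under 75 are out of scope (the claims system covering ages ≥ 75
  is the data source);
* within-municipality disparity is only partially visible at 500 m mesh
  resolution.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `code_set` | — | eight 9-digit codes | the fee-schedule definition of home medical care |
| `min_age` | years | 75 | cohort covered by the claims database |
| `fiscal_year` | — | 2019 | exact integer match; multi-year input must be pre-filtered |
| `n_trials` | — | 10 | the repeated-draw protocol |
| `distance_threshold_km` | km | 16 | national fee-table reference limit for home-visit distance |
| `time_threshold_min` | min | 30 | conventional exceedance threshold for travel time |
| `objective` | — | `"time"` | what "closest" minimizes; see below |
| `size_m` | m | 500 | the standard national population grid cell |
| `speed_kmh` per edge | km/h | by `road_class` | the claims data carry no speeds; a config map supplies them |

**Objective: time vs distance.** The source procedure reports both but does
not state which the closest-facility search minimized. We default to
travel time (the quantity clinicians experience) and report the distance of
the same time-optimal path; `cost_model(objective = "distance")` switches
the search, and the 16 km exceedance rule can be read against either run.

**Mesh interpretation.** "500 m mesh" is taken as 500 m × 500 m square
cells — the standard national grid — not 500 m². Cells are axis-aligned
squares stored as center + size; polygons are derived, never stored.
All coordinates are planar projected meters; readers never handle
geographic lat/lon internally.

## Randomness and reproducibility

One master seed governs a run. Per-(trial, municipality) substreams are
derived deterministically (a string hash of the municipality id plus a
trial offset, mod 2³¹ − 1), so adding or removing a municipality never
perturbs another's draws, and trial *t* is reproducible in isolation.
Both the cell allocation and the within-cell placement are redrawn each
trial (the repeated-trial protocol does not distinguish the two sources of
uncertainty; redrawing both is the conservative reading).

Allocation defaults to a **multinomial** draw with probabilities
`pop_i / Σ pop` — "randomly allocated, proportional in expectation" — with
a deterministic **largest-remainder** mode for runs that need exact
proportional rounding (ties go to the earlier cell). Cells with zero
population aged ≥ 75 can never receive patients in either mode.

**Shared draws across scenarios.** Within one study run the actual and
ideal scenarios see byte-identical patient sets. This makes the scenario
contrast a pure facility-set effect and turns the superset-monotonicity
property — each patient's ideal cost ≤ actual cost, hence every municipal
Δmedian ≥ 0 and Δrate ≥ 0 — into an exact invariant, which
`run_full_study()` asserts on every run rather than hoping for.

## Numerical choices

* **Percentiles** use linear interpolation (`stats::quantile` type 7),
  since published medians and IQRs carry one decimal.
* **Exceedance is strict** (`> 16 km`, `> 30 min`), matching "over" and
  "longer than".
* **Pooling.** Patient-level observations are pooled across trials before
  medians and rates are computed; per-trial summaries are also emitted
  (`summary_per_trial`) so an averaged-over-trials reading can be
  inspected. Pooling was chosen because the per-municipality observation
  counts in small municipalities are tiny within one trial.
* **Snapping.** Patients and facilities snap to the Euclidean-nearest
  network node, ties to the smallest node id. The snap leg is excluded
  from cost by default; `cost_model(access_leg = "straight_line")` adds the
  straight-line snap distances (and their traversal at `access_speed_kmh`)
  after the facility has been chosen on network cost, so the choice itself
  stays a network property.
* **Tie-breaks.** Equal-cost facilities resolve to the smallest facility
  id. Among several equal-cost optimal paths, the secondary metric is
  measured on the path the shortest-path search returns.
* **Unreachable patients** (disconnected network components) are retained
  with `reachable = FALSE`, excluded from percentiles, and counted as
  exceeding any threshold in the rate numerators and denominators — a
  patient with no route exceeds every limit. Their count is always
  reported.
* **Degenerate inputs.** A municipality with patients but no populated
  mesh cells, a scenario selecting no facilities, all-zero mesh
  populations with a positive count, and qualifying patients in a
  zero-population municipality are all hard, named errors rather than
  silent zeros.

## What the synthetic generator emulates — and what it does not

`generate_region()` builds a toy prefecture with the *statistical*
structure the analysis assumes: a compact, dense urban core (Gaussian
population kernel on the mesh); sparse, elongated rural municipalities
with only ~20% of cells populated; a lattice road network in which rural
non-spine edges are thinned (creating detours) and neighboring
municipalities connect through a single trunk corridor; facilities placed
where people live, with the provider subset biased toward urban
municipalities; and planted usage rates spanning roughly 1–10% of the
population aged ≥ 75, the range observed across real municipalities.
`generate_claims()` emits 1–k qualifying claims per planted patient, spread
so every true provider bills at least once, plus decoy claims that each
fail *exactly one* qualifying criterion (wrong code, age under 75, or
wrong fiscal year) so each filter clause is independently exercised; the
claims filter recovers the generator's ground truth exactly.

The generator does **not** imitate real geography: no actual municipal
shapes, no elevation or mountain-pass travel, no one-way streets or
congestion, no household clustering within cells, no real mesh-code or
address systems. Passing tests therefore demonstrate the *machinery* —
filtering, allocation, shortest paths, scenario arithmetic, invariants —
not the empirical travel times of any real prefecture, which depend on the
confidential claims data and real road networks this package deliberately
does not require.

Problem sizes in the shipped tests and demo were chosen so a full check
runs on a desk machine: the demo region has 3 municipalities, 136 network
nodes and 82 patients per trial across 10 trials; property sweeps use 20
generator seeds and 200 random graphs of up to 50 nodes against an
independent reference Dijkstra implementation.

## Known limitations

* No facility capacity or workload balancing; each patient is served by
  the closest facility regardless of demand.
* Travel cost ignores turn restrictions, one-way streets and time-of-day
  effects; edge speeds come from a user-supplied class map.
* The provider definition ("at least one qualifying claim") can include
  facilities that provide the service only incidentally.
* Percentile and rate estimates in municipalities with very few patients
  are noisy even after pooling 10 trials; the per-trial table makes that
  visible.
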