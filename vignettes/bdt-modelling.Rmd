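---
title: "Modelling beam delivery time for pulse-scanned proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling beam delivery time for pulse-scanned proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bdtmodel)
```

## The problem

In pencil-beam-scanned (PBS) proton therapy on a Hyperscan-type
synchrocyclotron, the beam is delivered as discrete proton *pulses*: each
planned *spot* (a transverse position and an energy) is delivered as one or
more pulses capped at about 8 pC each. The elapsed time between two
consecutive pulses, ΔT, spans four orders of magnitude and is governed by
what the machine has to move between them:

* nothing — pulses repeat within a spot or the aperture holds still:
  a few milliseconds;
* the **adaptive aperture (AA)**, a nozzle-mounted multi-leaf collimator
  that trims each spot's lateral penumbra: tens to hundreds of
  milliseconds, growing with the summed leaf travel;
* the **range modulator**, a stack of 18 degrader plates whose
  combinations realize 161 energy levels spaced 2.1 mm in water-equivalent
  thickness: energy-layer switches cost more than a second, growing with
  the number of plates repositioned.

Accurate per-pulse delivery-time prediction matters for 4D (interplay)
dose evaluation, volumetric repainting, delivery-time-aware plan
optimization and throughput estimation. `bdtmodel` implements the full
analysis pipeline — machine-log feature engineering, a random-forest ΔT
regressor, interval-stratified error analysis, Shapley explainability and
the two downstream applications — together with a synthetic machine-log
simulator, so that every stage is testable without institutional patient
log files.

## The synthetic machine model

`machine_config()` collects the physics constants: 161 energy levels at
2.1 mm WET spacing, an 18-plate range modulator, an 8 pC pulse cap, a 5 pC
low-charge verification layer, and 14 aperture leaves inside a
20 × 20 cm² field.

**Plate thicknesses** are not published; the simulator uses binary weights
(1, 2, 4, … 128 in spacing units) on the first 8 plates, the remaining 10
held as spares. This is the minimal scheme that reproduces the printed
level count and constant spacing, makes the level→plate mapping a
bijection, and gives "plates moved" (the Hamming distance between
occupancy vectors) a concrete meaning. A consequence worth knowing: a
one-level energy step can flip several plates (level 3 → 4 flips three),
so the energy-switch dead time is *not* a function of the energy delta
alone — the regression below genuinely cannot resolve it from the delta
features, which creates an irreducible error floor in the > 1000 ms bin,
mirroring what is observed on the real machine.

The printed 0–32.2 cm depth range is inconsistent with
160 × 2.1 mm = 33.6 cm; the simulator honors the level count and spacing
and does not use the range endpoint.

**Deterministic timing.** The inter-pulse time is an additive latency
model (all constants exposed in `timing_params()`, defaults in
milliseconds):

ΔT = 7 + 2·ΔS + 1·|Δq| + [ΔAA>0]·(50 + 2·ΔAA) + [ΔE≠0]·(900 + 120·plates)
  + 400·[low-charge→treatment] + 200·[first transition]

with ΔS the spot shift (mm), Δq the pulse-charge change (pC), ΔAA the
summed leaf travel (mm). The AA and energy constants place the three
regimes in their observed bands (no-change < 50 ms, aperture-only within
50–1000 ms, any energy change > 1000 ms). The small ΔS and |Δq| terms give
the sub-50 ms regime genuine structure (scanning/steering settling and
extraction-charge regulation); without them the short intervals would be
featureless, contradicting the observed ΔT–ΔS dependence and the
short-interval relevance of spot and charge features.

**Noise.** Fraction-to-fraction variability is zero-mean Gaussian with
sd = 0.5 ms + 0.08·ΔT (heteroscedastic: absolute error grows with the
interval, relative error shrinks), plus a rare positive outlier component
(probability 10⁻³, half-normal of scale 300 ms) representing sporadic
stalls. Inter-pulse times are truncated at 0.1 ms so timestamps stay
strictly increasing. These parameters reproduce the qualitative intrinsic
variability pattern (sub-2 ms MAE for short intervals growing to
~200 ms beyond a second, with ~99.9% of residuals within ±500 ms); no
claim is made of matching any institution's exact values.

**Plans.** Each beam opens with a low-charge copy of its first energy
layer (5 pC per pulse — the spot-position verification pass), followed by
treatment layers in descending energy. Spots follow a serpentine raster
(rows of 8–14 spots at 2.5 mm spacing with millimetre jitter); spot
charges are drawn uniformly from 2–30 pC and split into pulses
filled-to-cap (8, 8, …, remainder). The aperture follows the spot sequence
with a 12 mm dead band on the *accumulated* drift since its last
re-centering, plus occasional drift corrections (probability 0.05 per spot
move): leaves stay parked over several small in-row steps and jump when
the spot has wandered far enough or a row/layer changes. This yields the
composition that drives everything downstream: roughly 90% of transitions
below 50 ms, ~8% aperture moves spread over 50–1000 ms, and ~1% energy
switches beyond 1000 ms — the sharply peaked, heavy-tailed ΔT mix
characteristic of this machine type. The explainability structure
(aperture dominant globally, spot/charge dominant below 50 ms) is a
consequence of this composition; a simulator with, say, only a quarter of
its transitions in the fast regime would place the Shapley base value far
from the fast-regime predictions and hand the aperture feature a large
constant credit there instead.

What the simulator does **not** emulate: the vendor's proprietary spot
ordering, real leaf-bank mechanics (leaves are abstracted as 14 points on
a ring at 8 mm margin), gantry/couch motion, dose or range physics, and
any correlation structure of the noise across transitions. Passing the
synthetic recovery tests therefore demonstrates that the pipeline
faithfully extracts the structure this generator encodes — not that the
fitted constants transfer to any particular clinical machine.

## Feature engineering

One row per pulse transition (a record of N pulses gives N−1 rows):

| feature | meaning |
|---|---|
| `log_daa` | log1p of the summed leaf travel ΔAA = Σₗ √(ΔXₗ² + ΔYₗ²), mm |
| `log_ds` | log1p of the spot shift, mm |
| `delta_e`, `log_de` | signed energy-level difference and log1p of its magnitude |
| `charge`, `delta_charge` | destination pulse charge and its change, pC |
| `is_first_pulse` | transition out of a record's first pulse (start-up delay) |
| `is_tx_pulse` | transition from the last low-charge pulse to the first treatment pulse |

The first pulse of a record has no predecessor, so rows are transitions
and the first pulse contributes no target; `is_first_pulse` flags the
transition *out of* pulse 1. ΔE is carried in energy-level index units
(one unit = one 2.1 mm WET step) because the plate model is index-native.
The target is `log_delta_t = log1p(delta_t)`; predictions are mapped back
through `expm1` and clamped at zero before any millisecond-scale metric.

`stratified_split()` partitions rows 70/30 using quantile bins (default
10) of the log target, preserving the skewed distribution in both subsets.
Splitting is by transition row, not by fraction — the transitions of one
fraction can land in both subsets. For the synthetic study this mainly
tests interpolation; the held-out *plans* in the application stage are the
genuine generalization test.

## Model and evaluation

Numeric features are robust-scaled (median / inter-quartile range, linear
interpolation quantiles; constant columns fall back to scale 1); booleans
pass through. `tune_and_train()` runs a randomized search (default 8
draws) over tree count 100–500, depth {∞, 10–25}, minimum leaf size 1–20
and feature-subsampling fraction 0.3–1.0, scored by 5-fold CV mean
absolute error in log space, refits the best draw on all training rows,
and stores the scaler, forest, CV table and seed. Everything is seeded and
single-threaded by default so runs are bit-reproducible.

Errors are reported per reference-ΔT bin (0–50, 50–500, 500–1000,
> 1000 ms; half-open, binned by the reference because the true value is
unknown at inference): MAE in ms and MAPE in % of the reference.
The yardstick is `interfraction_variability()`: the same plan simulated
over fractions, fraction 1 as reference — the machine's own
reproducibility. On the default 55 k-transition study (3 beams × 18
layers × 40 spots × 10 fractions) the trained forest's per-bin MAE lands
at 0.65–0.75× the intrinsic MAE in every bin, against the acceptance bound
of 2×. A caveat the tests make visible: CV on global log-MAE prefers
smoother trees, which shrink the sparse 500–1000 ms aperture tail
downward (~ −5% there), producing a small systematic cumulative
underestimation — the synthetic analogue of the underestimation of long
delays observed with the real-data pipeline.

## Shapley explainability

Two independent routes compute the same quantity:

* `exact_shapley()` — brute-force enumeration of all 2^|N| coalitions of
  the Shapley formula (capped at 15 features);
* `tree_shap()` — an Rcpp pass over the forest that only branches where
  the explained instance and the background row diverge, exact in
  polynomial time per tree.

Both use the **interventional** value function: f(S) is the mean model
output over background rows of the hybrid input taking the features in S
from the instance and the rest from the background row. This choice is
deliberate: "the model prediction using only the features in S" is
otherwise ill-defined for a forest, and both routes must share one
convention or they measure different things. With it, additivity
(φ₀ + Σφᵢ = prediction, with φ₀ the mean background prediction) holds to
float accumulation, and the two routes agree to < 10⁻⁶ on the trained
forest — the module's central correctness test, alongside the dummy and
symmetry axioms on constructed models.

Features are grouped by subsystem (AA = {log_daa}, spot = {log_ds},
charge = {charge, delta_charge}, energy = {delta_e, log_de},
boolean = {flags}; user-overridable), group attributions being member
sums. Explanations are computed for 100 test instances drawn stratified
over target deciles, against a 100-row training background; attributions
are in the model's native log-target units. Global importance is the mean
|φ| per group; per-interval importance is the max |φ| per group within
bins of the *predicted* ΔT.

## Applications

**Volumetric repainting.** `make_repainted_plan()` repeats the treatment
layer sequence k times (default 5), each repaint boundary forcing a fresh
aperture and lowest-to-highest energy transition. The model — trained only
on non-repainted plans — predicts the timeline of the held-out repainted
plan; `compare_timing_sources()` reports the signed relative deviation of
the total delivery time (predicted minus reference). On the default study
this lands within a few percent (negative: long delays are slightly
underestimated), against the 5% acceptance bound, with the repaint-boundary
jumps clearly present in both cumulative curves.

**Interplay.** `map_pulses_to_phases()` assigns each pulse to a
respiratory bin (default 10 phases, uniform in time — the simplest
well-defined convention; displacement-amplitude binning would be a
config-level extension) of a sinusoidal trace with periods 2/4/5 s, and
accumulates charge per phase; charge is conserved exactly, and the phase
label never depends on the trace amplitude. Each beam's timeline starts
at phase 0 — delivery start is not synchronized to breathing, but the
same convention applies to every timing source, so comparisons are fair.
`interplay_experiment()` compares the model-predicted phase map against
the maps of (by default) ten simulated reference fractions: the model
passes when its mean total-variation distance to the fractions does not
exceed the largest fraction-to-fraction distance. A model *below* the
intrinsic minimum is treated as a pass — being closer than the machine's
own variability is success, not failure. Because both the model drift and
the intrinsic spread are stochastic, this criterion can be marginal at
the 2 s period on unlucky draws.

Dose recalculation (D98/D95/V95, DVHs) is out of scope: it requires a
4DCT and a dose engine; the pipeline deliberately stops at phase-resolved
charge maps and their distributional comparison.

## Numerical and reproducibility choices

* Timestamps, coordinates and charges are rounded to 0.001 units at
  generation so log files round-trip bit-stably through CSV.
* Every stochastic stage takes a seed; the end-to-end pipeline derives
  per-stage sub-seeds from the master seed with fixed offsets (+10
  simulation, +20 split, +30 training, +40 explanation, +50 application),
  so stages can be rerun in isolation.
* Degenerate inputs are defined, not accidental: constant scaler columns
  fall back to scale 1; quantile bins collapse with a warning on ties;
  a single-pulse record yields an empty feature table with a warning;
  phase indices guard the representable edge of the cycle.
* Problem sizes: the full synthetic study used by the acceptance tests is
  3 beams × 18 layers × 40 spots × 10 fractions (≈ 56 k pulses per
  fraction set, ≈ 55 k transitions) with a 6-draw hyperparameter search —
  large enough for all four ΔT bins to be populated and the importance
  structure to stabilize, small enough to run on one CPU in minutes.

## Known limitations

* The simulator's timing constants are calibrated to regime bands, not
  fitted to any machine; absolute MAE values are not comparable across
  installations.
* The forest under-predicts rare long delays (tail shrinkage); oversampling
  or quantile-aware scoring would be the natural extensions.
* `delta_e` in level units assumes the 2.1 mm grid; a MeV mapping would
  need the machine's energy-level table.
* Leakage control is by plan/beam identifiers; it assumes distinct plans
  carry distinct beam ids (the generator's `plan_id` guarantees this).
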