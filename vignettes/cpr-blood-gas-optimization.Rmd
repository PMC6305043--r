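---
title: "Optimizing blood gas delivery during CPR: model, optimizers, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing blood gas delivery during CPR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cproptim)
```

## The model

CPR alternates blocks of `x` chest compressions with single
positive-pressure ventilations. `cproptim` treats the procedure as a
steady-state gas-exchange system and scores it by **total blood gas
delivery**: systemic oxygen delivery plus carbon dioxide delivery to the
lungs, in mL gas per minute. Oxygen delivery keeps vital organs perfused;
CO₂ delivery to the lungs is what allows elimination and is the quantity
end-tidal CO₂ tracks clinically. Both matter, so their sum (optionally a
weighted sum, `weighted_total_delivery()`) is the objective.

Delivery of each gas is mean flow times concentration change,
`D = Q̄ · ΔC`. The pieces:

* **Mean blood flow.** Compressions drive flow only during the
  compression fraction of each cycle:
  `Q̄ = Q_max · x / (T/t + x)`. It vanishes with `x = 0`, rises
  monotonically with `x`, and saturates at the patient-specific maximum
  flow `Q_max` — more compressions per ventilation buy flow, with
  diminishing returns.
* **Alveolar fractions.** A steady-state mass balance over the lung sets
  the alveolar (= end-tidal) fraction of each gas from the balance of
  effective alveolar ventilation `(v_t − v_d)·R` against blood
  uptake/release `Q̄·s`:
  `f_A_O2 = (v_t − v_d)R f_I_O2 / ((v_t − v_d)R + Q̄ s_O2)` and
  `f_A_CO2 = (v_t − v_d)R f_I_CO2 / ((v_t − v_d)R − Q̄ s_CO2)`.
  Oxygen is absorbed (`f_A_O2 ≤ f_I_O2`), carbon dioxide released
  (`f_A_CO2 ≥ f_I_CO2`).
* **Concentration changes.** Within the linear range of the dissociation
  curves, `ΔC = s · f_A` with constant slopes `s_O2`, `s_CO2`.

Model assumptions worth keeping in mind: steady state within each
evaluation (no gas-store dynamics), balanced systemic and pulmonary flow
(one `Q_max` serves both pathways), linearized dissociation curves, and a
patient described by `Q_max` alone.

### The CO₂ singularity

When perfusion-driven CO₂ release outruns effective ventilation
(`(v_t − v_d)R ≤ Q̄ s_CO2`) the steady state has no physical solution:
the alveolar CO₂ fraction would be infinite. The package raises a typed
`cproptim_singularity_error` there instead of returning infinities, and
the optimizers treat such points as infeasible — a silent pole would
otherwise be an irresistible (and meaningless) attractor for the
annealer.

A related analytic point: as `v_t → v_d⁺` with `x > 0`, the oxygen
delivery is squeezed to zero (`D_O2 ≤ (v_t − v_d)·f_I_O2/t`), but the CO₂
delivery is **not** — numerator and denominator are both linear in
`v_t − v_d`, so `D_CO2` tends to a constant or diverges at the pole, and
the region beyond is infeasible. The tests assert the provable limits.

### Formula variants

The published closed-form delivery expressions are not mutually
consistent with the component equations above: the printed CO₂ delivery
numerator carries the O₂ slope and inspired O₂ fraction, and matching the
closed forms to the mass balance forces a ventilation rate of `R = 1/t`,
although one ventilation per full cycle gives `R = 1/(x·t + T)`. Rather
than guess intent, three variants are first-class and every downstream
function is parameterized by them:

* `as_printed` (default) — the closed forms verbatim; faithful to the
  publication. Internally it corresponds to `R = 1/t`.
* `corrected_co2` — the CO₂ numerator symbols swapped to the CO₂
  quantities (`s_CO2`, `f_I_CO2`). With typical inspired CO₂ near zero
  this makes `D_CO2` nearly negligible (≈ 0.22 vs ≈ 168 mL/min at the
  nominal point), which is why the variant choice matters scientifically.
* `explicit_R` — the full composition of flow, mass balance and
  concentration changes with the cycle-based `R = 1/(x·t + T)`. Because
  this `R` is much smaller, the CO₂ singularity arrives much earlier in
  the box; high-ratio/low-volume corners that are feasible under
  `as_printed` are infeasible here.

All three agree exactly on `D_O2` between `as_printed` and
`corrected_co2`, and all satisfy the structural limits (zero delivery at
`x = 0`, flow bounded by `Q_max`).

## Parameters, units and defaults

All times are minutes, volumes mL, flows mL/min, fractions dimensionless —
no unit conversions anywhere in the core.

| parameter | meaning | bounds (default) | nominal start |
|---|---|---|---|
| `T` | ventilation pause | 0.132–0.134 min | 0.133 |
| `t` | one compression | 0.008–0.012 min | 0.010 |
| `x` | compressions per ventilation | 5–100 (configurable) | 30 |
| `v_t` | tidal volume | 600–1000 mL | 800 |
| `f_I_O2` | inspired O₂ fraction | 0.13–0.19 | 0.16 |
| `f_I_CO2` | inspired CO₂ fraction | 0.0002–0.0006 | 0.0004 |
| `Q_max` | patient maximum flow | swept 700–1100 mL/min | — |
| `v_d`, `s_O2`, `s_CO2` | constants | 150 mL, 1.5, 0.8 | — |

Choices that were genuinely open:

* **Ratio bounds.** No published range exists for `x` even though it is
  optimized; `[5, 100]` brackets conventional 15:2 and 30:2 practice and
  the above-30 ratios the model itself favors, and is configurable
  (`default_bounds(x_range = ...)`).
* **Patient-group span.** Two presets exist (`q_max_range()`): the sweep
  default 700–1100 mL/min used by all experiments here, and a wider
  tabulated alternative 400–1000 mL/min.
* **Nominal start.** Bound midpoints with `x = 30`, the conventional
  ratio — "start from current practice".
* **Inspired fractions.** The `f_I_O2` range sits below the ambient 0.21;
  it is implemented as specified rather than silently widened.

## The annealer

`anneal()` is a bounded continuous simulated-annealing minimizer
(maximization is handled by negating the delivery objective once, at the
scheme layer):

* **Metropolis acceptance** — downhill always, uphill with probability
  `exp(−Δ/temperature)`.
* **Geometric cooling** — `t_{k+1} = cooling_factor · t_k` (default
  0.92) with a fixed number of proposals per level (default 100), from an
  initial temperature to `min_temperature` (default 10⁻³).
* **Initial temperature** — auto-calibrated from 100 seeded probe
  proposals at the start so the median uphill move is accepted with
  probability ≈ 0.8; a removable default, not a magic number. On
  landscapes whose start neighbourhood is flat (plateaus between narrow
  basins) the probes see only noise, so an explicit
  `initial_temperature` should be supplied there.
* **Proposals** — one randomly chosen coordinate per step, uniform draw
  of width `neighbor_scale · (upper − lower)` scaled by
  `sqrt(temperature/T₀)` (floored at 10%), with out-of-box excursions
  *reflected* back. Single-coordinate moves keep the acceptance rate
  useful in six dimensions at low temperature; joint all-coordinate moves
  froze runs ~1–2% short of the oracle optimum. Reflection rather than
  clipping avoids piling proposal mass onto corners, which matters
  because the delivery objective provably attains corner optima in
  several coordinates. The exported `propose_neighbor()` documents the
  all-coordinate generator used for calibration.
* **Infeasible points** (CO₂ singularity) return `NA` and are never
  accepted nor recorded as best.
* **Determinism** — a run is a pure function of (seed, config, start,
  objective); the caller's RNG state is untouched.

The free-energy diagnostic `free_energy()` connects the temperature to
the energy–entropy balance of a finite state set under Boltzmann
occupation; it is a conceptual companion to the acceptance rule, not part
of the search loop.

## The two schemes

**Global** (`global_optimize()`): one annealing run over all six rescuer
parameters at fixed `Q_max`; the trajectory records the best state per
temperature level.

**Sequential** (`sequential_optimize()`): per CPR cycle, anneal `x` alone
(the rescuer then performs the cycle — the `ratio_step` record), then
anneal the five remaining parameters with `x` fixed (`others_step`),
warm-starting each sub-run at the incumbent best. Warm starting makes the
per-cycle best delivery non-decreasing by construction. Both sub-runs are
budgeted by `per_cycle_budget` proposals (default 300). Both phases score
the same weighted total delivery; scoring the second phase by oxygen
delivery alone changes nothing here, because the two objectives share
their maximizer over the non-ratio parameters in this model.

Two knobs shape the sequential trajectory:

* **Stopping.** "Improved by less than `convergence_tol` (default 10⁻⁴
  relative) for `patience` (default 3) consecutive cycles" — the model
  supplies no stopping rule of its own.
* **Rate limit.** Optionally, each parameter may move at most
  `rate_limit · (bound width)` per cycle. It is **off by default** (the
  minimal faithful reading); switching it on produces the gradual
  cycle-by-cycle drift of ratio and compression speed that one expects
  from a dynamically adapting protocol. Reported trajectory *shapes*
  therefore depend on this knob, and `qualitative_trends()` records (but
  never asserts) the drift patterns per run.

A structural caveat the package surfaces honestly: the delivery objective
is static — nothing in it changes from cycle to cycle — so at convergence
the sequential scheme cannot beat the global optimum, and both schemes
agree to within a fraction of a percent (asserted at 1%). Claims that
per-cycle adaptation outperforms a fixed optimum require a time-varying
element (e.g. depletion of blood oxygen stores) that this model does not
contain; the sweep reports both final and trajectory values so the
comparison is visible, but the package does not assert a winner.

## Oracle validation

`grid_search()` evaluates the objective on a uniform endpoint-inclusive
grid (default 9 points per dimension ≈ 5.3 × 10⁵ points over six
parameters, vectorized, capped at 10⁷) and returns the exact grid
maximum. Endpoints are included deliberately: corner optima are real for
this objective, so corners must be on the grid. The test suite requires
the annealed optimum to be within 0.5% of the grid maximum; in practice
the worst observed shortfall across seeds is ~0.1%, and the continuous
optimum frequently exceeds the coarse grid's.

## The synthetic cohort and what the tests show

`generate_patient_cohort()` draws `Q_max` uniformly over 700–1100 mL/min:
patients differ only in maximum achievable flow. That emulates the one
axis of patient variation the model represents; it does not emulate
real-data features like measurement noise, intra-patient drift over the
resuscitation, or covariation of lung mechanics with perfusion. Passing
tests therefore demonstrate the *method* — correct model algebra,
optimizers that reach verified optima, reproducibility — not clinical
validity. The results' direction (higher `Q_max` ⇒ higher achievable
delivery, strictly, for both schemes) is asserted as a structural check.

## Numerical choices, degenerate inputs

* The CO₂ denominator crossing zero raises a typed error everywhere in
  scalar paths and yields `NA` + `feasible = FALSE` in vectorized paths.
* Zero-width bounds pin a parameter exactly; a bounds box collapsed to a
  point makes every optimizer return that point's direct evaluation.
* Ties on the grid resolve to the first index in column-major order —
  relevant only where a parameter (e.g. `f_I_CO2` under `as_printed`)
  does not enter the objective.
* CSVs are written with full double round-trip precision; re-reading a
  trajectory and re-evaluating the model reproduces every reported
  delivery to ≤ 10⁻⁹ relative.
* Default problem sizes (chosen to keep a full desk experiment under a
  minute): ~11k proposals per global run, 300 proposals per sequential
  phase with ≤ 40 cycles, five patient groups, 9-points-per-dimension
  oracle grids.

## Known limitations

* Static physiology: no gas-store depletion, no time-varying `Q_max`, so
  cycle-by-cycle adaptation cannot (and does not) beat the static
  optimum.
* The `as_printed` CO₂ delivery inherits the publication's internal
  inconsistency; conclusions sensitive to the CO₂ pathway should be
  checked under `corrected_co2` and `explicit_R` (the package makes this
  a one-argument change).
* Linearized dissociation curves: inaccurate far from the operating
  range, by construction.
* The optimum routinely sits on bound corners, so results are only as
  meaningful as the clinical bounds supplied.
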