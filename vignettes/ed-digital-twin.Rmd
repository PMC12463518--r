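---
title: "An emergency-department digital twin: model, calibration and designed experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An emergency-department digital twin: model, calibration and designed experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edtwin)
```

## The model and its assumptions

`edtwin` represents an emergency department as a discrete-event system:
patients are entities that compete for seven capacity-constrained
resource pools (registration agents, triage nurses, triage beds,
technicians, and per-zone physicians, nurses and beds) across an adult
and a pediatric zone. The model deliberately covers only mid-acuity
walk-in flow (ESI levels 3–4); resuscitation-level and fast-track
patients follow different pathways and are out of scope, as is inpatient
admission downstream of the ED.

Key structural assumptions:

* **Arrivals** form a non-homogeneous Poisson process. The 24-hour rate
  profile is piecewise-constant per hour and sampled by thinning
  against its maximum, so zero-rate hours receive no arrivals exactly.
* **Registration and triage are parallel branches.** Real timestamp
  logs routinely show the registration clerk finishing *after* the
  triage nurse has seen the patient, so the model starts both on
  arrival and requires both before bed placement. The `Reg` milestone
  is therefore the only one allowed to violate the otherwise monotone
  ordering `arrive ≤ triage ≤ bed ≤ doc ≤ discharge`.
* **The zone bed is an occupancy contract.** It is seized at bed
  assignment and held until the discharge process completes, even
  while the patient is also consuming physician or nurse time. Task
  tables that mark beds only on later rows are read as "actively
  engaged", not as "first seized here".
* **Queues are FIFO within a zone.** No acuity-based preemption is
  modelled: with only ESI 3–4 in scope, priority routing would be
  speculative. Multi-resource requests (e.g. physician + zone nurse)
  are granted atomically when all members are free; a blocked request
  does not prevent a later, satisfiable one from proceeding.
* **The system drains.** Arrivals stop at the horizon but events run to
  completion, so every arrival is eventually discharged (unless a
  required pool has zero capacity, which raises an unbounded-queue
  warning instead of deadlocking silently). Conservation — arrivals =
  discharged + in-system — is checked per replication.

## Service-time laws and their conventions

All service times are given as strings in the conventional simulation
notation (`TRI`, `GAMMA`, `LOGNORM`, `EXPO`, `CONST`, with optional
affine pre-factors `b + a * FAMILY(...)`). Three conventions deserve
explicit statement because the notation is ambiguous across tools:

* `GAMMA(shape, scale, min)` and `LOGNORM(log-mean, log-sd, min)` treat
  a third parameter as a minimum shift added to the variate — the
  convention of the commercial tool family the source model was built
  in. This is an assumption, not a verified fact; it is isolated in
  `parse_distribution()` and trivially changed.
* An ill-ordered triangular triple (the default triage-notes task is
  printed as `1.7 * TRIA (1, 0.3, 10.1)`, with mode < min) is sorted
  into `(min, mode, max)` with a logged warning rather than rejected:
  the model must run with the published inputs.
* Affine-transformed variates are truncated at zero (durations), with
  the truncation count recorded on the sample.

Every law has closed-form moments (`dist_moments()`), which the test
suite checks against Monte-Carlo at fixed seeds. One numerical caveat:
the consultation-notes law `LOGNORM(1.3, 2, 1)` has log-sd 2 and hence
an astronomically heavy tail (kurtosis of order e^16). Its sample
*mean* converges acceptably; its sample *variance* does not at any
test-scale n, so the variance check is restricted to families with
tame fourth moments. This is a property of the published input, not of
the implementation.

## Randomness, reproducibility, common random numbers

Every stochastic element — arrival thinning, the zone/acuity mixes,
routing, and each (task, zone) pair — draws from its own named
substream, seeded deterministically from `(seed, id, replication)`.
Two design choices matter:

* **Entity-level pre-assignment.** All of a patient's service durations
  and routing decisions are drawn when the patient arrives, not when
  each task starts. Since arrival sequences are identical across
  scenarios sharing a seed, scenario comparisons (DOE points,
  calibration evaluations) see *synchronized* common random numbers:
  the same patient brings the same demands everywhere, and differences
  between design points reflect capacity, not sampling noise. The test
  suite verifies the variance reduction directly.
* **Replication offsets.** Replications differ only in the `rep` term
  folded into each substream seed, so `run_scenario()` is bit-for-bit
  reproducible and each replication is distinct.

## Default parameter choices (the stated world)

Several quantities any real deployment would measure are not published
for the case study; they are configuration defaults here, chosen once:

| parameter | default | rationale |
|---|---|---|
| arrival profile | raised-cosine, peak 11:00, peak:trough 3:1 | smooth unimodal daytime peak; the published profile figure prints no numbers |
| arrival volume | 72 patients/day | keeps the baseline resource set loaded but stable (adult-nurse utilisation ≈ 0.7); the hospital's 129k annual census is context, not a target |
| zone mix | P(peds) = 0.3 | typical mixed-ED share; configurable |
| acuity mix | P(ESI 3) = 0.5 | unprinted; only recorded, not used in routing |
| test routing | CT 0.25, X-ray 0.25, lab 0.30, none 0.20 | exercises every task row; unprinted |
| reassessment | one pass, loop probability 0 | single reassessment is the modal pathway |
| physicians | 4 adult, 2 peds | never published; meant to be *calibrated*, and sized so physicians are not the binding constraint at baseline |
| triage nurses, registration, technicians | 2 each | same status |
| horizon / warm-up / replications | 14 d / 1 d / 10 | matches a two-week evaluation with up-to-ten replications |

The experimental factor levels default to the published ones: triage
beds (1, 2, 3), adult nurses (7, 9, 11), peds nurses (5, 7, 9), adult
beds (20, 26, 32), peds beds (8, 10, 12). The engine takes levels
verbatim from configuration; it does not re-derive ±25% percentages,
because the printed level table and the percentage description disagree
and the table is the more specific statement.

## KPIs and validation

`compute_kpis()` pools post-warm-up patients across replications and
reports AtT, AtD and LOS means with standard errors. LOS1/LOS2 default
to the adult/pediatric zones; the stratum rule is explicit because the
reference table never states what its two LOS rows stratify by — zone,
acuity and discharge status are all plausible, and all three are
selectable.

Validation uses the signed (not absolute) percentage difference
`(sim − real)/real × 100`, kept unrounded in machine output; integer
rounding is applied only in the display column. The worked reference
rows behave exactly as published arithmetic requires: (15, 15) → 0;
(91, 80) → 13.75, displayed 14; (225, 224) → 0.45, displayed 0. The
(193, 184) row computes 4.89 while the source prints "4.8"; the
package reports 4.89 and the acceptance test checks the source's own
textual claim ("below 5%") rather than the garbled digit.

## The designed experiment and its analysis

`full_factorial()` enumerates 3^k points in deterministic lexicographic
order; `run_design()` maps each point onto capacities and simulates it
under CRN. Per-zone 3-factor designs (27 points) are the default —
the published analyses are per zone — and a joint 5-factor design (243
points) is built the same way if asked.

`fit_ols()` regresses replication-level responses on **raw capacity
units** (nurses, beds), matching the parameterization of the published
equations; coded −1/0/+1 units and point-mean responses are flags, not
defaults. Adult-zone models use main effects plus all two-way
interactions; pediatric models add the three-way term, mirroring the
published term sets.

ANOVA uses **partial (Type III-style) F tests** computed from
full-versus-reduced residual sums of squares. This choice is not
cosmetic: with raw (uncentered) numeric regressors, main effects and
their interactions are correlated even on a balanced factorial, so
sequential (Type I) sums of squares would depend on term order.
Partial tests are order-invariant and reduce to the classical balanced
ANOVA under coded units. Degenerate cases are handled explicitly: a
saturated model (zero residual df) is an error; a zero-residual fit
(noiseless responses) flags infinite F rather than crashing. Displayed
p values below 0.001 print as `<0.001`; raw values are retained.

Standardized effects are |t| statistics from the replication-level fit;
the Pareto table ranks them, and main-effect/interaction cell-mean
tables are exported plot-ready. On a balanced design the level means of
any factor average exactly to the grand mean — a property the tests
assert.

The published regression coefficients and F tables themselves are *not*
reproduction targets: they depend on unpublished arrival magnitudes,
routing probabilities and the confidential hospital log. What the
package establishes instead is property-based: noiseless responses
generated from each published equation at its 27 design points are
refit to machine precision (R² = 100%), the OLS path agrees with an
explicit normal-equations oracle, the null-factor F test rejects at its
nominal 5% rate, and a planted nurse bottleneck is ranked first by the
pipeline end to end — the qualitative headline of the case study.

## Calibration

`calibrate()` stands in for the proprietary optimizer used in the
original study. It minimizes a discrepancy — by default the sum of
squared KPI percentage differences, the same currency as the validation
table — over box-bounded free parameters using Nelder–Mead with
projection onto the bounds, restarts after stagnation, and a hard
evaluation budget. Because every evaluation reuses the scenario seed,
the objective is quasi-deterministic (exactly zero at a self-generated
target), which lets a derivative-free simplex work on what would
otherwise be a noisy simulation response. Budget exhaustion returns a
non-converged result, never an exception. `qq_pp()` provides the
distribution-level diagnostics (histogram, P-P, Q-Q, maximum quantile
gap) for comparing simulated and reference duration distributions.

## What the synthetic data does and does not establish

`generate_event_log()` emits milestone logs in the hospital CSV schema
(`Arrive,Reg,Triage,Bed,Doc,Discharge,Room,Discharge status`, zones
`"Zone A"`/`"PEDS"`), by default in the information-losing
minute-resolution `MM/DD HH:MM` stamp style of real exports — the
lossless minutes dialect exists behind a flag and is what KPI tests
use. The generator is the simulator itself, so a green test establishes
internal consistency (KPI code, validation, DOE and calibration all
recover planted truths), **not** fidelity to any real ED: real logs
have data-entry errors, left-behind patients, admit/transfer outcomes,
shift-dependent service rates and minute-rounding artifacts that the
synthetic world does not contain. The minute rounding alone can move
short-duration KPIs (AtT) by tens of percent — one reason validation
against minute-stamped references should use the lossless dialect
internally.

## Numerical choices and degenerate inputs

* Triangular sampling is inverse-CDF; degenerate `TRI(a, a, a)`
  collapses to a constant at parse time.
* The queueing engine asserts `in-use ≤ capacity` at every grant and
  non-negative counts at every release.
* An all-zero arrival profile is a valid scenario producing an empty
  log; an empty post-warm-up log is an explicit error in
  `compute_kpis()`, never NaN.
* `erlang_c_wait()` computes the M/M/c waiting time on the log scale to
  stay stable at high offered load.
* Config hashes are 32-bit polynomial hashes — identification, not
  cryptography.

## Known limitations

* Shift schedules are supported structurally (constant capacity per
  pool by default) but no published rosters exist to default to.
* Whether technicians are shared across zones is unstated; they are
  modelled as shared.
* The simulator is pure R; a 14-day, 10-replication baseline runs in
  tens of seconds, which is ample for desk-scale studies but would
  motivate a compiled event loop for thousand-point designs.
* Calibration identifiability is the user's responsibility: a free
  parameter that the chosen KPIs do not respond to (e.g. arrival scale
  under unlimited resources) cannot be recovered.
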