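# edtwin

A desk-scale digital twin of an emergency department (ED). The package
is aimed at health-systems operations analysts who want to test staffing
and bed-capacity interventions *in silico* before touching a real ward:
it simulates patient flow as a discrete-event system, validates the
simulated key performance indicators (KPIs) against reference
statistics, explores resource configurations with a three-level
full-factorial experiment, and summarizes the results with interaction
regressions, partial-F ANOVA and a Pareto ranking of standardized
effects.

## The model

Patients of acuity ESI 3–4 arrive at the ED by a non-homogeneous
Poisson process with a 24-hour rate profile λ(t), and are routed to the
adult or pediatric zone. After arrival, **registration** (registration
agent) and **triage** (triage bed + triage nurse) run as parallel
branches — a registration clerk may finish after the triage nurse has
already seen the patient — and both must complete before a **zone bed**
is assigned. The bed is held until discharge. On the bed the patient
receives a **physician consultation** (physician + zone nurse), **nurse
notes**, optionally one **test** (CT, X-ray or lab; zone nurse +
technician), one or more **reassessment** passes (physician + zone
nurse) and finally the **discharge process** (zone nurse), after which
all resources are released.

Service times follow textbook laws written in conventional simulation
notation — e.g. `TRI (2, 3, 5)` for registration,
`1 + 2 * Gamma (0.1, 2.5, 2.5)` for triage, `LogNORM (1.3, 2, 1)` for
physician notes — parsed by `parse_distribution()` and sampled from
named random substreams so that scenarios sharing a seed share common
random numbers (CRN).

The KPIs are the field's standard ones, in minutes:

* **AtT** — arrival to triage,
* **AtD** — arrival to doctor (door-to-doctor),
* **LOS** — length of stay (arrival to discharge), reported overall and
  per stratum (LOS1 = adult zone, LOS2 = pediatric zone by default).

Validation uses the signed percentage difference

    (Simulated − Real) / Real × 100

and the factorial machinery fits, per zone and response, ordinary least
squares in raw capacity units

    y = β₀ + β₁·TriageBed + β₂·ZoneNurse + β₃·ZoneBed + (2-way, 3-way interactions) + ε

with per-term partial-F tests and standardized effects |t| for the
Pareto chart.

## Worked example

Simulate the baseline scenario and validate against reference KPIs:

```r
library(edtwin)
cfg <- scenario_config(horizon_days = 3, warmup_days = 0.5,
                       replications = 3, seed = 42)
kp <- compute_kpis(run_scenario(cfg))
ref <- data.frame(variable = c("AtT", "AtD", "LOS1", "LOS2"),
                  real_minutes = c(15, 80, 184, 224))
validate_kpis(kp, ref)
```

```
KPI validation (signed percentage difference)
  variable real simulated pct_diff reported
1      AtT   15     31.53   110.19      110
2      AtD   80     52.70   -34.13      -34
3     LOS1  184    213.42    15.99       16
4     LOS2  224    188.81   -15.71      -16
LOS rows within 5%: no
```

Each row compares a simulated mean with its reference value; `reported`
is the integer-rounded display form, `pct_diff` the raw statistic. The
default (uncalibrated) scenario misses the illustrative reference here
— that is the starting point for `calibrate()`, which tunes free
parameters (e.g. the arrival-volume scale) by box-constrained
Nelder–Mead under CRN.

Run a 3³ factorial over triage beds, adult nurses and adult beds on a
deliberately nurse-constrained scenario and rank the effects:

```r
base <- scenario_config(arrival_profile = generate_arrival_profile(60, 11, 3),
                        horizon_days = 1.5, warmup_days = 0.25,
                        replications = 3, seed = 17,
                        capacities = list(triage_nurse = 5))
facs <- list(doe_factor("TriageBed", c(2, 3, 4), "bed_triage"),
             doe_factor("ZoneNurse", c(4, 5, 6), "nurse_adult"),
             doe_factor("ZoneBed", c(20, 26, 32), "bed_adult"))
rt <- run_design(full_factorial(facs), base, zone = "adult")
fit <- fit_ols(rt, "LOS")
effect_summaries(rt, fit)$pareto
```

```
                 term       effect rank
1           ZoneNurse 0.6658736303    1
2   ZoneNurse:ZoneBed 0.0864497569    2
3             ZoneBed 0.0828539048    3
4           TriageBed 0.0043585411    4
5 TriageBed:ZoneNurse 0.0018438091    5
6   TriageBed:ZoneBed 0.0006837911    6
```

Zone nurse staffing dominates LOS in this configuration — the planted
bottleneck is recovered by the experiment-and-regression pipeline. The
accompanying `fit` prints the regression equation
(`LOS = 935.8 - 1.001 TriageBed - 122.3 ZoneNurse + ...`,
R-sq = 23.76%) and `effects_anova(fit)` the per-term F and p values.

A command-line front end lives in `inst/cli/edtwin.R`
(`simulate`, `validate`, `doe`, `analyze`, `synth-log`,
`synth-profile`).

## Documentation

See the methods vignette (`vignettes/ed-digital-twin.Rmd`) for the
model's assumptions, default parameter choices, what the synthetic data
does and does not emulate, and known limitations.
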