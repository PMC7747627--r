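---
title: "Models and methods behind heattent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heattent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heattent)
```

# The problem

High night temperature (HNT) stress during grain filling reduces winter
wheat yield and starch concentration. Studying it in the field requires
holding heated "stress" tents a fixed temperature differential above
paired, unheated "control" tents, all night, for weeks — a job done by a
per-tent thermostat controller reading a six-sensor array once per minute
and switching a propane heater through a relay. This package implements
that controller faithfully enough to audit its logic, a paired-tent
microclimate simulator to exercise it in closed loop, and the
environmental and agronomic statistics used to judge the outcome.

# The control law

The controller is deliberately simple, and the implementation preserves
that:

* **Aggregate**: the arithmetic mean of the sensors that read successfully
  this minute. Zero successful reads is a *failed cycle* — data for the
  fault policy, never an exception.
* **Decide**: heater ON iff `stress_avg − control_avg < setpoint_diff_C`
  (default 4.0 °C). The boundary case — a differential of exactly the
  setpoint — resolves to OFF ("at or above the setpoint, do not engage").
  There is **no hysteresis band**: the source rule is a single threshold,
  and the one-minute decision cadence itself prevents relay
  short-cycling. Decisions are only permitted inside the active window
  (19:00–06:00); outside it the relay is forced off.
* **Paired message**: the control tent transmits its aggregate each
  minute. The stress controller caches the last message and coasts on it;
  once the cache is older than `stale_msg_max_min` (default 5 min) the
  fail-safe is heater OFF with a logged `stale_msg` health token. The
  fail-safe direction is a design choice the source system leaves
  unstated: we prefer under-heating plus a warning to uncontrolled
  heating.
* **Fault policy**: each failed cycle increments a consecutive-error
  counter; at `max_consec_errors` (default 5) the controller "reboots"
  (counters and message cache reset, heater forced off for that cycle,
  health `rebooted`); after `max_reboots` (default 3) it sets a permanent
  `degraded` flag but *keeps looping* — the field policy is to stay online
  and preserve the experiment. The counts 5/3/5-min are configuration
  defaults, exposed because the source describes "a set number" without
  stating values. Reboot latency is not modeled (no stated duration).
* **Clocking**: the controller reasons in local wall-clock time (the role
  of the hardware RTC); all timestamps are timezone-naive, stored as UTC
  `POSIXct` so no DST arithmetic can ever corrupt a schedule.

# The microclimate model

Each tent is one well-mixed air node (lumped capacitance), first order in
time, advanced by explicit Euler at the 1-minute cadence that the sensing
loop imposes anyway:

$$T_{t+1} = T_t + \Delta t \left[ k(\text{vent}) (T_{amb} + b - T_t)
  + q_h \cdot \mathbb{1}[\text{heater}] \right]$$

* `k_closed = 0.07 min⁻¹`, `k_open = 0.5 min⁻¹`: a closed tent has a
  ~14-minute time constant; an open or gap-vented tent tracks ambient
  within ~2 minutes. The night "control gap" setting (walls 20 cm above
  the baseboard, ambient air circulating) uses `k_open`.
* `q_heat = 0.5 °C min⁻¹`: sized so the heater is non-limiting,
  `q_heat/k_closed ≈ 7 °C` ≥ 6 °C above ambient at steady state —
  consistent with an 82,000 BTU/h unit in a 9.1 × 14.6 m tent. The
  steady-state elevation `q_heat/k_closed` is exact even for the discrete
  Euler update, and the test suite checks it in closed form.
* `day_bias_C = 0.4 °C`: open-vent greenhouse offset of the plastic skin,
  applied only in the open state.
* Spatial nonuniformity is represented **only** through per-sensor fixed
  biases, because uniformity is evaluated in the field as inter-sensor
  differentials, not as a spatial field. Default array: six biases evenly
  spaced over ±0.5 °C with 0.25 °C Gaussian read noise (the sensor
  sensitivity envelope), giving a time-averaged mean absolute pairwise
  difference of ≈ 0.52 °C — the few-tenths-of-a-degree regime a
  well-mixed tent achieves.
* **Moisture**: the tent's actual vapor pressure relaxes toward ambient
  vapor pressure at the same ventilation rate; in a *closed* tent it
  instead relaxes toward ambient RH plus `rh_gain` points (default 15)
  evaluated at tent temperature — a lumped canopy-transpiration source.
  RH is recomputed at the new temperature and clipped to [0, 100].
  Saturation vapor pressure uses the Magnus form with FAO-56 constants
  (0.6108, 17.27, 237.3), over air temperature, consistently here and in
  `vpd_kPa()` — the VPD formula is a package choice since none is given
  by the source system.
* **CO₂**: night respiration source (1.08 ppm min⁻¹) minus leakage toward
  a 457 ppm base, leak rate 0.01 min⁻¹ closed and scaled up for gap/open
  states: a closed stress tent drifts from ~457 ppm at closing toward a
  ~565 ppm source/leak equilibrium over the night.
* **Ambient driver**: diurnal sinusoid (daily max 15:30, min 03:30) plus
  stationary AR(1) noise (φ = 0.8 per minute, sd 0.3 °C), defaults 18 ± 6
  °C. A sinusoid was chosen over replayed weather so the package is fully
  self-contained; recorded minute CSVs can be substituted through
  `read_ambient()` with no other change.

## What the simulator does and does not establish

The simulator targets the *control law's* behaviour, not any particular
season's weather. A green closed-loop test establishes that the bang-bang
loop holds the stress window differential inside [3.4, 4.1] °C — a band
containing the +3.8 °C a real season achieved with the same law — and
that overshoot is bounded by `q_heat·Δt` plus sensor noise. It does *not*
reproduce field magnitudes that depend on weather (absolute tent means,
RH curves, CO₂ extremes), radiative and wind effects absent from a
single-node model, heater duct transients, or spatial gradients beyond
fixed sensor biases. Two deliberate small infidelities: the no-heat null
is exactly zero only under constant ambient (under a diurnal ramp the
closed tent lags ambient more than the gapped one, a real physical
effect of order +0.2 °C), and the simulated controller is rebooted at
power-on each evening, so fault counters do not carry across nights.

# Trait analysis

* **Percent differences** are `100·(HNT − control)/control`, rounded half
  away from zero to 2 decimals (table convention; R's `round()` would
  bank's-round exact halves). The overall row of a trait table is the
  percent difference of the *means of the per-genotype means*
  (mean-of-means): on the packaged starch table this reproduces the
  printed −15.31 exactly, whereas the mean of per-genotype percent
  differences gives −14.97; the latter is still reported as a secondary
  statistic. Eight of 24 packaged rows recompute exactly; the rest differ
  by ≤ 0.06 because the published table evidently used unrounded raw
  means — `reproduce_table3()` classifies these `approx` against a 0.1
  tolerance rather than asserting false precision.
* **Per-°C statistics** divide a percent response by the imposed
  differential; ΔT defaults to 3.8 °C in the CLI but is always an
  explicit argument, never inferred from data silently.
* **Split-plot ANOVA**: temperature is the whole-plot factor (2 levels
  over 3 tent pairs, so the T test has only 4 error df), genotype and T×G
  are sub-plot terms. Replicated rows (the check line) are first averaged
  to one value per genotype × treatment × tent; the balanced sums of
  squares are then computed directly, which is exact, matches
  `stats::aov()` with an `Error(tent)` stratum to machine precision (a
  cross-check in the test suite keeps both routes honest), and is fast
  enough for thousand-rep calibration simulations.
* **Tukey letters**: with a common error MS and equal replication, two
  means separate iff their difference exceeds a single HSD constant, so
  compact letter groups are exactly the maximal windows of the sorted
  means with span below the HSD; groups are lettered from the largest
  mean down, ties resolved by sort order.
* **Check-line uniformity** compares blocks 1–4 vs 5–8 of the check
  genotype within each tent with a one-way F test — a pure positional
  signal test whose null false-alarm rate the suite verifies at α.
* **Emergence index** uses the speed-of-emergence form Σ(newly emerged on
  day d)/d, the common choice where the source's citation is not
  reproduced; the form is echoed in the output metadata and the argument
  exists for alternatives.
* **Fusarium extrapolation** multiplies mean single-seed weight of
  non-infected seed by total seed count; it reduces to the identity when
  infection is absent, and a Monte-Carlo test confirms the extrapolated
  vs whole-sample treatment response correlates at R² > 0.9 when the
  infection penalty is treatment-independent.

# The synthetic trait generator

`generate_trait_data()` emulates the field layout: 12 genotypes × 2
treatments × 3 tent pairs, eleven genotypes one row per tent (random
block of 8), the check genotype (Everest) in every block. The model is

$$y = \mu_c (1 + e/100 \cdot \mathbb{1}[\text{HNT}]) (1 + \gamma_g)
  + \tau_{tent} + \varepsilon$$

with genotype effects multiplicative (shared across treatments, so
percent responses are genotype-stable) and tent and residual noise
additive. Control means and treatment effects default to the published
main-effect means (so, e.g., grain yield 512.8 g m⁻² with a −17.1 %
effect); the variance components are fixed once at values typical of
replicated wheat trials — genotype CV 0.10, between-tent CV 0.03,
residual CV 0.08 on single 0.5-m row samples — and are not tuned
thereafter. Under these defaults the split-plot T test is calibrated
(type-I ≈ 0.05 against 1000 null datasets) and detects a 15 % reduction
in well over 80 % of runs, and the round-trip summary recovers injected
effects within Monte-Carlo error. The generator does not emulate spatial
block trends, genotype × tent interactions, non-normal residuals, or
missing plots — so green calibration tests certify the estimator under
the stated model, not robustness to those departures.

# Numerical and interface choices

* Explicit Euler at 1-minute steps matches the sensing cadence; the only
  stiffness (k_open = 0.5) keeps `1 − kΔt` well inside stability.
* Log pairing across tents is by exact timestamp, no interpolation: both
  streams are minute-aligned by construction, and silent interpolation
  could mask logger faults.
* `NA` tokens (never empty fields) encode failed reads in the CSV schema,
  keeping the column count fixed and malformed rows detectable by field
  count, reported with line numbers.
* Fixture CSVs are checksummed at load; an edited fixture fails every
  consumer immediately.
* All randomness flows through R's RNG seeded once per run; a fixed seed
  gives byte-identical logs, which the suite asserts at file level.

# Known limitations

Single-node thermal physics (no radiation, wind, soil coupling); RH/CO₂
dynamics are plausible lumped models, not calibrated moisture physics;
the bang-bang analysis assumes minute-aligned synchronous tents; the
split-plot implementation requires balance after aggregation and two
treatments; compact letters assume the constant-HSD (equal replication)
case. These mirror the scope of the system being modeled rather than
accidental gaps.
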