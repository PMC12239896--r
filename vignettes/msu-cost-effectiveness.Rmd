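---
title: "Modelling the cost-effectiveness of mobile stroke unit dispatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of mobile stroke unit dispatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msucea)
```

## The decision problem

A mobile stroke unit (MSU) carries a CT scanner, point-of-care laboratory
and telemedicine link, so an ischemic stroke patient can receive
intravenous thrombolysis (IVT) on scene and a large vessel occlusion (LVO)
can be recognised in the field and driven straight to a
thrombectomy-capable stroke center (TSC) instead of via a primary stroke
center (PSC). Both IVT and endovascular thrombectomy (EVT) have strongly
time-dependent benefit, so minutes saved translate into better functional
outcome, which translates into more quality-adjusted life years (QALYs) and
lower long-term care costs. Against that stand the costs of buying and
operating the unit. This package implements a state-transition
microsimulation that weighs the two over the remaining lifetime of one
year's suspected-stroke patients, and compares dispatch scenarios
(site, operating hours, catchment) through the incremental net monetary
benefit (iNMB).

The model is deliberately region-agnostic: everything specific to a region
(populations per zone, hospitals and their workflow times, driving times,
dispatch sites) enters as data, and a synthetic-region generator provides a
fully specified stand-in for development, testing and method exploration.

## What the synthetic region emulates — and what it does not

`generate_synthetic_region()` scatters zones over a planar square (default
about 1,600 km²), gives them populations that decay away from an urban core
(e-folding distance 12 km by default) and an approximately national 5-year
age structure with mild zone-level jitter, places TSCs near the core and
PSCs across the region, and derives travel times as Euclidean distance at a
mean road speed of 60 km/h inflated by a detour factor of 1.3 — a standard
approximation of road-network distance. Defaults are sized to a region of
1.77 million inhabitants served by 7 PSCs and 2 TSCs; the default age-band
incidence profile is calibrated so that such a region produces roughly
5,500 suspected-stroke alarms per year, around two thirds of them alerting
within 6 hours of onset, with a median patient age in the mid-70s.

What it does not emulate: real road topology (rivers, bridges, congestion),
diurnal and seasonal alarm patterns (a configurable diurnal weight vector
exists but defaults to uniform), correlations between deprivation, age and
stroke risk, and hospital-level workflow variation beyond random
hospital-specific constants. Tests that pass on synthetic regions therefore
establish the correctness and internal consistency of the *machinery*, not
the external validity of any particular regional estimate — for a real
application the four region CSVs and the YAML parameter file should carry
measured values.

## Cohort and eligibility

Suspected-stroke counts are Poisson per (zone, age band) with mean
population × rate, diagnoses are multinomial (stroke mimic, TIA,
intracerebral hemorrhage (ICH), ischemic stroke without/with LVO; defaults
28% / 12% / 8% / 40% / 12%, i.e. 23% of ischemic strokes are LVO), alarm
clock-times are uniform over the year, and the onset-to-alarm delay is a
mixture of a short-delay spike (25% of alarms, uniform 5–60 minutes,
representing witnessed onsets) and a heavy-tailed log-normal whose location
is solved so that 66% of alarms fall under the 6-hour gate. Only the
sub-6-hour patients enter the dispatch model; the gate is applied to the
true onset-to-alarm time (a dispatcher-estimation error model would sit
between the two and is out of scope).

Each patient record retains the uniform draw behind their diagnosis. When a
sensitivity analysis perturbs the diagnosis-mix probabilities, the
diagnosis is re-derived from the same uniform, so the cohort's structure
(who, where, when) is held fixed while the diagnosis responds to the
parameter — common random numbers applied at the diagnosis level. This is
what makes diagnosis-mix parameters visible to the PSA and the tornado even
though the cohort itself is generated once.

## Dispatch and the busy model

The MSU responds when the alarm falls inside the daily operating window
(base case 07:00–23:00), the zone lies within the catchment limit (driving
time from the MSU site; the boundary counts as inside), and the unit is
free. Reasons for non-dispatch are recorded in that order of precedence.
The busy interval is: drive to scene + total on-scene time + escort to the
receiving hospital + return to base. Each leg is configurable; setting
`msu_escort_to_hospital = FALSE` models a unit that hands the patient to
the EMS at the scene and returns directly. Dispatch is decided by the alarm
time only — a mission that will end after closing time is still started.
EMS capacity is not modelled (a conventional ambulance is always
available), and one MSU is the default, though the sweep accepts `n_units`
with first-free assignment.

Availability is reported as dispatches divided by eligible alarms arising
*inside the catchment*, which is how per-scenario availability is
conventionally tabulated; the count of all eligible alarms is returned
alongside so either denominator can be formed.

## Time composition

All treatment times decompose into explicit legs (minutes):

* MSU arm: `OTT_IVT = onset-to-alarm + dispatch-to-arrival +
  on-scene-to-needle`; for LVO, `OTT_EVT = onset-to-alarm +
  dispatch-to-arrival + total-on-scene + drive(zone→TSC) + door-to-groin`.
* EMS arm: `OTT_IVT = onset-to-alarm + dispatch-to-arrival + on-scene +
  drive(zone→nearest center) + door-to-needle`; for LVO at a TSC,
  door-to-groin replaces door-to-needle; for LVO at a PSC the drip-and-ship
  path adds door-in-door-out, the PSC→TSC drive, a fixed handover and the
  receiving TSC's door-to-groin (optionally shortened by a pre-notification
  factor, default 1 = no benefit).

Driving legs and on-scene times carry multiplicative log-normal noise with
mean 1 (log-sd 0.2 by default); each patient's noise uniforms are drawn
once and reused in both arms, so a patient who is "slow on scene" is slow
in both strategies. The MSU's on-scene time is split into time-to-needle
(default mean 23 min) and total on-scene (33 min), since the needle goes in
before departure. When both vehicles are dispatched the EMS transport leg
is taken from the (shared) arrival at scene; arrival-time interleaving
between the two vehicles is not modelled separately.

## Outcome model

Untreated 90-day mRS distributions for non-LVO ischemic stroke, LVO
ischemic stroke and ICH are model inputs. Treatment shifts the ischemic
distributions by a proportional-odds move: for every cut k in 0..5,
`logit P(mRS <= k)` increases by

    delta(t) = max(0, beta + beta_decay * t),   t = onset-to-treatment time,

inside the treatment window (4.5 h for IVT, 6 h for EVT) and 0 outside it.
The defaults (`beta_ivt = 1.1`, decay −0.0035/min; `beta_evt = 1.5`, decay
−0.003/min) are anchored to the magnitude and slope of pooled ordinal
trial reanalyses of IVT and EVT benefit by time to treatment; they are
stand-ins for regionally estimated coefficients, which is why they are
front-and-center in the PSA and tornado defaults. Design choices worth
making explicit:

* the shift includes mRS 6, so treatment reduces 90-day mortality, in line
  with full-scale ordinal shift analyses;
* for LVO patients receiving both IVT and EVT the log-odds effects add
  (`additive_lvo_effects = FALSE` switches to the larger single effect);
* the floor at zero means late treatment is never modelled as harmful —
  the decayed effect simply vanishes;
* cumulative probabilities of exactly 0 or 1 are clamped to
  `[1e-12, 1 − 1e-12]` before the logit so degenerate distributions pass
  through unchanged.

Treatment receipt is two Bernoulli draws — probability 0.55 of IVT for an
ischemic stroke inside 4.5 h and 0.85 of EVT for an LVO inside 6 h — made
once per patient and shared across strategies, so the same patient is a
"treatment taker" in both arms and the comparison isolates the timing
effect. Mimics end in a non-stroke state, TIA in mRS 0, ICH in its own
distribution, all identical across strategies by construction.

The realized state is drawn by inverting the patient's shared uniform
against the cumulative distribution, which couples the two arms: a patient
whose MSU-arm distribution stochastically dominates the EMS-arm one can
only move to an equal or better state, never worse, which removes a large
amount of comparison noise.

## Lifetime values

From the 90-day state onward patients stay put until death (no recurrent
stroke, no state transitions after 90 days). Cycles are 3 months, 9 months,
then annual, 100 in total (99 years of horizon — the first two cycles
compose year one), after which everyone is assumed dead. Utilities
(defaults 0.95 / 0.93 / 0.83 / 0.62 / 0.42 / 0.11 for mRS 0–5, 0 for death)
and annual long-term costs (EUR 1.5k / 3.5k / 7k / 18k / 38k / 46k) accrue
pro rata; discounting is applied at cycle midpoints (1.5% effects, 4.0%
costs — no additional within-first-year discounting beyond the midpoint
convention) and the cycle of death is credited at half weight (half-cycle
correction). Mortality applies the age-specific annual hazard — a
Gompertz–Makeham approximation of a contemporary west-European life table —
multiplied on the hazard scale by an mRS-specific hazard ratio (defaults
1.0–5.0); the annual death probability is `1 − (1 − q_age)^HR`. No extra
mortality is applied inside the first (90-day) cycle, because acute deaths
already enter as mRS 6; beyond age 110 death within the cycle is certain.
The non-stroke state (mimics) carries its own utility/cost keys, defaulting
to near-mRS-0 values.

Because a fixed state until death makes the expected discounted accrual a
closed form, the engine evaluates patients by the exact
survival-weighted sum conditional on their drawn 90-day state — unbiased
for the microsimulated value and much less noisy. `lifetime_value()`
exposes both modes, and the test suite holds the microsimulation mean to
within three standard errors of the closed form in every state at 10,000
draws.

Acute costs (EMS ride always; MSU ride when dispatched; IVT/EVT when given;
interhospital transfer when an EVT patient reached the TSC via a PSC; minus
the bypassed emergency-department cost when thrombolysis happened in the
MSU) are treated as incurred at time zero and not discounted. The MSU
program cost — investment depreciated over 5 years plus annual operating
and personnel costs — is added once to the MSU+EMS strategy, scaled by the
implementation horizon (default 1 year).

## Uncertainty analysis

The PSA draws one parameter set per iteration (beta distributions for
probabilities and utilities, gamma for costs, normal for the treatment
log-odds coefficients with the decay bounded above by zero; out-of-bound
draws are redrawn, with clamping and a warning after 100 rejections),
evaluates both strategies on the fixed cohort with common random numbers,
and records the deltas. Iterations are organised in runs — 3,000 iterations
and 10 runs in a full analysis — where each run re-seeds the patient-level
draws; reported means average all draws and 95% intervals are the 2.5/97.5
percentiles of the pooled draws (percentile, not normal-approximation;
pooling all draws rather than the run means is the default, the run means
remain accessible in the draws table). The dispatch sweep is computed once
per run from the base diagnosis mix: availability is reported as a
per-scenario operational statistic, not a parameter-uncertain quantity.
Everything is reproducible bit-for-bit from the master seed; scenario grids
share that seed so the EMS comparator is effectively common across
scenarios.

The tornado analysis substitutes each parameter's low/high value one at a
time (all else at base), reports per-strategy totals as well as deltas, and
orders rows by iNMB swing. The scaled problem sizes used throughout the
test suite — regions of 10⁴–10⁵ inhabitants, cohorts of a few hundred, PSAs
of 100–300 iterations × 1–2 runs — were chosen as the smallest sizes at
which every identity, oracle comparison and monotonicity property is
informative; the same code paths run unchanged at full scale.

## Numerical conventions and degenerate inputs

* Ties in nearest-hospital selection break by lexicographic hospital id.
* The catchment boundary (travel time exactly equal to the limit) is
  inside.
* A zone travel matrix must cover every (site, zone) and (zone, hospital)
  pair; missing pairs, dangling ids, negative times, or workflow times on
  the wrong hospital type (door-to-groin on a non-TSC, door-in-door-out on
  a TSC) are validation errors that name the offending row.
* The PSC→TSC transfer leg uses the hospital-to-hospital travel time when
  the matrix provides it and falls back to the zone→TSC time otherwise.
* An LVO pathway in a region without any TSC is a configuration error.
* Empty cohorts, empty operating windows and zero-incidence regions are
  valid inputs that produce empty (not erroneous) results.
* Seeds are plain integers; every derived seed stays below 2³¹.

## Known limitations

Onset-to-alarm and dispatch-time distributions, outcome baselines,
treatment-effect coefficients, utilities and costs ship as documented
stand-ins, not regional estimates — conclusions about any real region
require replacing them. Diagnostic accuracy is assumed equal between MSU
and in-hospital imaging; prehospital triage instruments, ICH treatment
effects, recurrent stroke, pre-existing morbidity, EMS fleet capacity and
societal-perspective costs are out of scope. The iNMB-by-year trajectory
attributes acute and program costs to year one and long-term flows to their
cycle years; other attributions (e.g. spreading depreciation over five
calendar years) would shift the break-even year without changing the total.
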