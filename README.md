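# msucea

State-transition microsimulation for the lifetime cost-effectiveness of
adding a **mobile stroke unit (MSU)** — an ambulance with an on-board CT
scanner that can start intravenous thrombolysis (IVT) in the field and
triage large vessel occlusions (LVO) straight to a thrombectomy-capable
stroke center (TSC) — to regular emergency dispatch for suspected stroke.

The package is aimed at health-economic modellers and stroke-system
planners who want to ask, for *their* region: given the population and its
age structure, the hospitals and their workflow times, and the driving
times between them, is it worth operating an MSU, and from which site, with
which operating hours and catchment?

## The model

One year of suspected-stroke alarms is simulated patient by patient:

1. **Region** — zones with age-stratified populations, primary stroke
   centers (PSC), TSCs, and dispatch sites, tied together by a travel-time
   matrix. Synthetic regions emulating a mixed urban/rural area of 1.77
   million inhabitants (7 PSC, 2 TSC) can be generated, or a real region
   supplied as four CSV files.
2. **Cohort** — suspected-stroke counts are Poisson per (zone, age band)
   with age-specific rates; each patient gets a diagnosis (stroke mimic,
   TIA, intracerebral hemorrhage, ischemic stroke with/without LVO), an
   onset-to-alarm delay and an alarm clock time. Patients alerting within
   6 hours of onset enter the model.
3. **Dispatch** — a chronological sweep decides for every alarm whether the
   MSU responds (inside operating hours, inside the catchment, unit not
   already on a mission).
4. **Times** — onset-to-treatment times for IVT and EVT are composed from
   alarm delay, dispatch-to-arrival, on-scene time, driving times and
   hospital workflow times (door-to-needle, door-to-groin,
   door-in-door-out), including the drip-and-ship transfer pathway for LVO
   patients first taken to a PSC.
5. **Outcomes** — the 90-day modified Rankin Scale (mRS) distribution is a
   proportional-odds shift of an untreated baseline: on every cumulative
   cut, `logit P(mRS <= k)` gains `max(0, beta + beta_decay * OTT)` per
   treatment, so each minute of delay erodes the benefit.
6. **Lifetime economics** — patients stay in their 90-day state until
   death. A 3-month cycle, a 9-month cycle and annual cycles thereafter
   (100 cycles total) accrue utilities and long-term costs with mid-cycle
   discounting (1.5% effects, 4.0% costs) and half-cycle correction;
   mortality applies age-specific hazards scaled by mRS-specific hazard
   ratios. Acute costs (rides, treatments, transfers, bypassed emergency
   department) and the MSU program cost (depreciated investment, operating
   and personnel costs) complete the ledger.
7. **Comparison** — the MSU+EMS strategy is compared with EMS-alone on the
   same patients with common random numbers. The headline quantity is the
   incremental net monetary benefit,
   `iNMB = dQALY x WTP − dCost` at a willingness to pay of EUR 50,000 per
   QALY, with probabilistic sensitivity analysis (PSA), scenario grids over
   sites x operating windows x catchments, and one-way tornado analysis.

Default parameter values are documented stand-ins chosen from registry-style
and trial-style sources; they are meant to be replaced with regional
estimates via the YAML configuration (`write_config()` / `read_config()`).

## Worked example

```r
library(msucea)

region <- generate_synthetic_region(n_zones = 30, total_population = 1e5, seed = 1)
region
#> Study region: 30 zones, 100,000 inhabitants
#>   hospitals: 7 PSC, 2 TSC
#>   dispatch sites: A, B, C

cohort <- generate_cohort(region, seed = 1)
summarize_cohort(cohort)[c("n", "n_eligible", "median_age")]
#> $n           321
#> $n_eligible  206
#> $median_age  76

cfg <- model_config()
scale <- 1e5 / 1.77e6   # size the MSU program to the scaled region
cfg$econ$msu_program <- lapply(cfg$econ$msu_program,
                               function(x) x * scale)
cfg$econ$msu_program$depreciation_years <- 5

base <- scenario_spec("A", window_hours = c(7, 23), catchment_min = Inf)
res <- run_psa(cohort, region, base, cfg, n_iterations = 300, n_runs = 2, seed = 1)
res
#> Scenario: A 07:00-23:00 entire region
#>   MSU dispatches: 132 (availability 64.1%)
#>   delta QALY: 6.8 (-3.2 to 22.2)
#>   delta cost (EUR million): 0.16 (-0.23 to 0.47)
#>   iNMB (EUR million): 0.18 (-0.56 to 1.32)
```

Of the 321 simulated suspected-stroke alarms, 206 occur within 6 hours of
onset; the MSU reaches 132 of them (64% availability) under a 16-hour
operating day. Over the cohort's remaining lifetime the MSU strategy gains
about 7 QALYs at a small net cost increase for this down-scaled region, for
a positive mean iNMB of EUR 0.18 million — with wide uncertainty, as the
95% interval shows. `run_scenario_grid()` sweeps operating windows and
catchment limits, `tornado()` ranks parameter influence, and
`export_results()` writes the results table, PSA draws, scatter data and a
JSON summary.

A thin command-line wrapper with the same verbs (`synth-region`, `cohort`,
`run`, `grid`, `tornado`) is installed under `inst/cli/msu-cea.R`.

## Package layout

- `R/region.R`, `R/cohort.R` — study region and virtual cohort
- `R/dispatch.R`, `R/times.R` — MSU availability and treatment times
- `R/outcomes.R`, `R/lifetime_econ.R` — 90-day outcomes and lifetime values
- `R/engine.R`, `R/psa.R`, `R/config.R` — strategy comparison, PSA,
  scenario grid, tornado, I/O
- `vignettes/msu-cost-effectiveness.Rmd` — methods: model structure,
  parameter meanings and defaults, numerical conventions, limitations
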