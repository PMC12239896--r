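Package: msucea
Title: Cost-Effectiveness Microsimulation of Mobile Stroke Unit Dispatch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: State-transition microsimulation model for the lifetime
    cost-effectiveness of adding a mobile stroke unit (MSU) to emergency
    dispatch for suspected stroke. Generates synthetic study regions
    (postal-code-like zones, stroke centers, dispatch sites, travel times)
    and one-year virtual cohorts of suspected stroke presentations,
    simulates MSU availability under configurable operating hours and
    catchment limits, composes onset-to-treatment times for thrombolysis
    and thrombectomy under each strategy, maps treatment and delay to
    90-day modified Rankin Scale distributions through a proportional-odds
    shift with per-minute decay of treatment effect, accrues discounted
    quality-adjusted life years and costs over the remaining lifetime, and
    compares strategies through probabilistic sensitivity analysis,
    scenario grids, and incremental net monetary benefit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
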