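test_that("with all components zeroed, ott_ivt reduces to onset-to-alarm", {
  r <- region(zones = make_zones("Z1", 0, 0),
              hospitals = make_hospitals("H1", tsc = TRUE, dtn = 0, dtg = 0),
              sites = make_sites("A"),
              travel = make_travel("A|Z1" = 0, "Z1|H1" = 0, "A|H1" = 0))
  tp <- quiet_times(ems_activation_min = 0, msu_activation_min = 0,
                    ems_on_scene_mean = 0, msu_on_scene_to_needle_mean = 0,
                    msu_on_scene_total_mean = 0, transfer_handover_min = 0)
  sc <- scenario_spec("A", c(0, 24), Inf)
  p <- make_patients(1, onset = 47)
  for (disp in c(TRUE, FALSE)) {
    bd <- pathway_times(p, disp, r, sc, tp, seed = 1)
    expect_equal(bd$ott_ivt, 47)
  }
})

test_that("drip-and-ship EVT time equals the hand-summed timeline", {
  # one zone, PSC 20 min away, TSC 40 min, dido 30, PSC->TSC 5, handover 10,
  # dtg 30; EMS activation 2, on-scene 25
  r <- toy_region(dido = 30, transfer = 5, dtg = 30)
  tp <- quiet_times(transfer_handover_min = 10)
  sc <- scenario_spec("A", c(0, 24), Inf)
  p <- make_patients(1, diagnosis = "ischemic_lvo", onset = 60)
  bd <- pathway_times(p, FALSE, r, sc, tp, seed = 1)
  expect_equal(bd$routing, "ems_via_psc")
  # 60 + (2 + 10) + 25 + 20 + 30 + 5 + 10 + 30
  expect_equal(bd$ott_evt, 60 + 12 + 25 + 20 + 30 + 5 + 10 + 30)
  # and the breakdown columns re-add to the same total
  expect_equal(bd$onset_to_alarm + bd$dispatch_to_arrival + bd$on_scene +
                 bd$scene_to_hospital + bd$dido + bd$transfer + bd$dtg,
               bd$ott_evt)
})

test_that("MSU and EMS arms share onset-to-alarm (common random numbers)", {
  w <- small_world()
  elig <- w$cohort[w$cohort$eligible, ][1:30, ]
  class(elig) <- c("msu_cohort", "data.frame")
  sc <- scenario_spec("A", c(0, 24), Inf)
  crn <- msucea:::draw_crn(30, 99)
  bd1 <- compute_pathway_times(elig, rep(TRUE, 30), w$region, sc,
                               time_params(), crn)
  bd2 <- compute_pathway_times(elig, rep(FALSE, 30), w$region, sc,
                               time_params(), crn)
  expect_equal(bd1$onset_to_alarm, bd2$onset_to_alarm)
})

test_that("component-sum identities hold on random regions", {
  for (seed in 1:5) {
    r <- generate_synthetic_region(n_zones = 8, total_population = 5e3,
                                   n_psc = 2, n_tsc = 1, seed = seed)
    set.seed(seed)
    n <- 30
    co <- data.frame(
      patient_id = sprintf("P%03d", 1:n), age = 74,
      zone_id = sample(r$zones$zone_id, n, replace = TRUE),
      diagnosis = sample(c("ischemic_nonlvo", "ischemic_lvo"), n,
                         replace = TRUE),
      onset_to_alarm_min = runif(n, 10, 300),
      alarm_time_min = runif(n, 0, 525600), eligible = TRUE, u_diag = 0.5,
      stringsAsFactors = FALSE)
    class(co) <- c("msu_cohort", "data.frame")
    sc <- scenario_spec("A", c(0, 24), Inf)
    crn <- msucea:::draw_crn(n, seed)
    disp <- runif(n) < 0.5
    bd <- compute_pathway_times(co, disp, r, sc, time_params(), crn)
    expect_true(all(bd$ott_ivt >= 0))
    lvo <- co$diagnosis == "ischemic_lvo"
    expect_true(all(!is.na(bd$ott_evt[lvo])))
    expect_true(all(is.na(bd$ott_evt[!lvo])))

    msu_rows <- disp
    expect_equal(bd$ott_ivt[msu_rows],
                 (bd$onset_to_alarm + bd$dispatch_to_arrival)[msu_rows] +
                   time_params()$msu_on_scene_to_needle_mean /
                   time_params()$msu_on_scene_total_mean *
                   bd$on_scene[msu_rows])
    ems_rows <- !disp
    expect_equal(bd$ott_ivt[ems_rows],
                 (bd$onset_to_alarm + bd$dispatch_to_arrival + bd$on_scene +
                    bd$scene_to_hospital + bd$dtn)[ems_rows])
    # transfers occur exactly on the ems_via_psc routing
    expect_equal(!is.na(bd$transfer), bd$routing == "ems_via_psc")
  }
})

test_that("MSU wins on thrombolysis when its needle time is shorter than
           the downstream EMS path", {
  r <- toy_region()
  tp <- quiet_times()
  sc <- scenario_spec("A", c(0, 24), Inf)
  p <- make_patients(1, onset = 30)
  bd_msu <- pathway_times(p, TRUE, r, sc, tp, seed = 2)
  bd_ems <- pathway_times(p, FALSE, r, sc, tp, seed = 2)
  # identical dispatch-to-arrival legs (same site, no noise), so the MSU is
  # faster iff needle-on-scene < on-scene + travel + door-to-needle
  expect_lt(bd_msu$ott_ivt, bd_ems$ott_ivt)
  expect_equal(bd_ems$ott_ivt - bd_msu$ott_ivt,
               (25 + 20 + 25) - 23)
})

test_that("eliminating dido and transfer shrinks the via-PSC saving by
           exactly those components", {
  sc <- scenario_spec("A", c(0, 24), Inf)
  p <- make_patients(1, diagnosis = "ischemic_lvo", onset = 30)
  saving <- function(dido, transfer, handover) {
    r <- toy_region(dido = dido, transfer = transfer)
    tp <- quiet_times(transfer_handover_min = handover)
    bd_msu <- pathway_times(p, TRUE, r, sc, tp, seed = 3)
    bd_ems <- pathway_times(p, FALSE, r, sc, tp, seed = 3)
    bd_ems$ott_evt - bd_msu$ott_evt
  }
  s_full <- saving(30, 5, 10)
  s_none <- saving(0, 0, 0)
  expect_equal(s_full - s_none, 30 + 5 + 10)
})

test_that("time-savings summary is invariant to cohort ordering", {
  w <- small_world()
  elig <- w$cohort[w$cohort$eligible, ][1:60, ]
  class(elig) <- c("msu_cohort", "data.frame")
  sc <- scenario_spec("A", c(0, 24), Inf)
  crn <- msucea:::draw_crn(60, 7)
  disp <- rep(c(TRUE, FALSE), 30)
  bd_m <- compute_pathway_times(elig, disp, w$region, sc, time_params(), crn)
  bd_e <- compute_pathway_times(elig, rep(FALSE, 60), w$region, sc,
                                time_params(), crn)
  s1 <- time_savings_summary(elig, bd_m, bd_e, disp)

  perm <- sample(60)
  elig2 <- elig[perm, ]; class(elig2) <- c("msu_cohort", "data.frame")
  s2 <- time_savings_summary(elig2, bd_m[perm, ], bd_e[perm, ], disp[perm])
  expect_equal(s1, s2)
})

test_that("identical arms yield zero savings", {
  # if the MSU contributes nothing distinct (same activation, same scene
  # time, needle = scene end, and the patient is non-LVO at a zone whose
  # nearest hospital is at distance 0 with dtn 0) the paths coincide
  r <- region(zones = make_zones("Z1", 0, 0),
              hospitals = make_hospitals("H1", tsc = TRUE, dtn = 0, dtg = 0),
              sites = make_sites("A"),
              travel = make_travel("A|Z1" = 5, "Z1|H1" = 0, "A|H1" = 5))
  tp <- quiet_times(ems_on_scene_mean = 30, msu_on_scene_to_needle_mean = 30,
                    msu_on_scene_total_mean = 30)
  sc <- scenario_spec("A", c(0, 24), Inf)
  p <- make_patients(1)
  bd_msu <- pathway_times(p, TRUE, r, sc, tp, seed = 4)
  bd_ems <- pathway_times(p, FALSE, r, sc, tp, seed = 4)
  expect_equal(bd_msu$ott_ivt, bd_ems$ott_ivt)
})

test_that("LVO pathway without any TSC is a configuration error", {
  r <- region(zones = make_zones("Z1", 0, 0),
              hospitals = make_hospitals("H1", tsc = FALSE),
              sites = make_sites("A"),
              travel = make_travel("A|Z1" = 5, "Z1|H1" = 10))
  p <- make_patients(1, diagnosis = "ischemic_lvo")
  expect_error(pathway_times(p, FALSE, r, scenario_spec("A", c(0, 24), Inf),
                             quiet_times(), seed = 1),
               "thrombectomy-capable")
})
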