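test_that("iNMB arithmetic behaves and stores exactly per draw", {
  expect_equal(inmb(0, 0, 50000), 0)
  expect_equal(inmb(10, -5000, 50000), 505000)
  w <- small_world()
  sc <- scenario_spec("A", c(7, 23), Inf)
  res <- run_psa(w$cohort, w$region, sc, model_config(),
                 n_iterations = 20, n_runs = 1, seed = 3)
  expect_equal(res$draws$inmb,
               res$draws$delta_qaly * 50000 - res$draws$delta_cost)
  # interval bounds ordered
  expect_true(all(res$summary$lo95 <= res$summary$hi95))
})

test_that("fixed distributions collapse the PSA to identical iterations", {
  w <- small_world()
  sc <- scenario_spec("A", c(7, 23), Inf)
  psa <- list(param_dist("beta_ivt", c("outcome", "beta_ivt"), "fixed",
                         list(value = 1.0)))
  res <- run_psa(w$cohort, w$region, sc, model_config(), psa = psa,
                 n_iterations = 15, n_runs = 1, seed = 5)
  expect_equal(length(unique(res$draws$inmb)), 1L)
  expect_equal(res$summary$lo95, res$summary$hi95)
})

test_that("a single iteration and run is a deterministic evaluation", {
  w <- small_world()
  sc <- scenario_spec("A", c(7, 23), Inf)
  r1 <- run_psa(w$cohort, w$region, sc, model_config(), psa = list(),
                n_iterations = 1, n_runs = 1, seed = 9)
  r2 <- run_psa(w$cohort, w$region, sc, model_config(), psa = list(),
                n_iterations = 1, n_runs = 1, seed = 9)
  expect_identical(r1$draws, r2$draws)
  expect_equal(nrow(r1$draws), 1L)
})

test_that("the null-effect configuration produces exactly zero deltas", {
  w <- small_world()
  sc <- scenario_spec("A", c(7, 23), Inf)
  res <- evaluate_strategies(w$cohort, w$region, sc, null_effect_config(),
                             seed = 21)
  expect_equal(res$delta_qaly, 0)
  expect_equal(res$delta_cost, 0)
  expect_equal(res$inmb, 0)
})

test_that("confidence interval width shrinks like one over root n", {
  w <- small_world()
  co <- w$cohort[w$cohort$eligible, ][1:80, ]
  class(co) <- c("msu_cohort", "data.frame")
  sc <- scenario_spec("A", c(7, 23), Inf)
  width <- function(n_it) {
    res <- run_psa(co, w$region, sc, model_config(),
                   n_iterations = n_it, n_runs = 1, seed = 13)
    s <- res$summary
    s$hi95[s$quantity == "inmb"] - s$lo95[s$quantity == "inmb"]
  }
  # percentile-interval width is a population quantity: it stabilises (does
  # not blow up) as iterations grow; the SE of the mean shrinks ~ 1/sqrt(n)
  res400 <- run_psa(co, w$region, sc, model_config(),
                    n_iterations = 400, n_runs = 1, seed = 13)
  res100 <- run_psa(co, w$region, sc, model_config(),
                    n_iterations = 100, n_runs = 1, seed = 13)
  se100 <- stats::sd(res100$draws$inmb) / sqrt(100)
  se400 <- stats::sd(res400$draws$inmb) / sqrt(400)
  expect_lt(se400, se100)
  expect_equal(se100 / se400, 2, tolerance = 0.5)
})

test_that("seeded PSA runs are bit-reproducible", {
  w <- small_world()
  sc <- scenario_spec("A", c(7, 23), 25)
  r1 <- run_psa(w$cohort, w$region, sc, model_config(),
                n_iterations = 10, n_runs = 2, seed = 77)
  r2 <- run_psa(w$cohort, w$region, sc, model_config(),
                n_iterations = 10, n_runs = 2, seed = 77)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$summary, r2$summary)
})

test_that("scenario grid rows mirror dispatch monotonicity", {
  w <- small_world()
  g <- run_scenario_grid(w$cohort, w$region, model_config(), sites = "A",
                         windows = list(c(9, 21), c(7, 23), c(0, 24)),
                         catchments = Inf, psa = list(),
                         n_iterations = 1, n_runs = 1, seed = 2)
  tab <- g$table
  expect_equal(nrow(tab), 3L)
  n_by_window <- tab$n_dispatches[match(c("09:00-21:00", "07:00-23:00",
                                          "00:00-24:00"), tab$window)]
  expect_true(all(diff(n_by_window) >= 0))

  g2 <- run_scenario_grid(w$cohort, w$region, model_config(), sites = "A",
                          windows = list(c(7, 23)),
                          catchments = c(Inf, 25, 20, 15), psa = list(),
                          n_iterations = 1, n_runs = 1, seed = 2)
  # eligible patients inside the catchment shrink with the limit
  ncatch <- vapply(g2$results, function(r) r$n_eligible_in_catchment,
                   numeric(1))
  expect_true(all(diff(ncatch) <= 0))
})

test_that("a one-scenario grid reproduces run_psa", {
  w <- small_world()
  g <- run_scenario_grid(w$cohort, w$region, model_config(), sites = "A",
                         windows = list(c(7, 23)), catchments = Inf,
                         psa = list(), n_iterations = 2, n_runs = 1,
                         seed = 31)
  direct <- run_psa(w$cohort, w$region, scenario_spec("A", c(7, 23), Inf),
                    model_config(), psa = list(), n_iterations = 2,
                    n_runs = 1, seed = 31)
  expect_equal(g$results[[1]]$draws, direct$draws)
})

test_that("tornado bars respond one parameter at a time", {
  w <- small_world()
  sc <- scenario_spec("A", c(7, 23), Inf)
  cfg <- model_config()
  ranges <- list(
    degenerate = list(path = c("outcome", "beta_ivt"), low = 1.1,
                      high = 1.1),
    p_mimic = list(path = c("epi", "p_mimic"), low = 0.22, high = 0.34),
    msu_ride = list(path = c("econ", "acute_costs", "msu_ride"),
                    low = 900, high = 2700))
  tor <- tornado(w$cohort, w$region, sc, cfg, ranges, seed = 6)
  # a degenerate range has a zero-width bar
  dg <- tor[tor$parameter == "degenerate", ]
  expect_equal(dg$swing_inmb, 0)
  # more mimics/TIA raise effectiveness and lower costs in BOTH strategies
  pm <- tor[tor$parameter == "p_mimic", ]
  expect_gt(pm$qaly_msu_high, pm$qaly_msu_low)
  expect_gt(pm$qaly_ems_high, pm$qaly_ems_low)
  expect_lt(pm$cost_msu_high, pm$cost_msu_low)
  expect_lt(pm$cost_ems_high, pm$cost_ems_low)
  # a parameter that only touches the MSU arm leaves EMS totals untouched
  mr <- tor[tor$parameter == "msu_ride", ]
  expect_equal(mr$qaly_ems_low, mr$qaly_ems_high)
  expect_equal(mr$cost_ems_low, mr$cost_ems_high)
  expect_gt(mr$cost_msu_high, mr$cost_msu_low)
  expect_error(tornado(w$cohort, w$region, sc, cfg,
                       c(ranges, ranges["p_mimic"])), "duplicate")
})

test_that("exports round-trip and have the documented shapes", {
  w <- small_world()
  sc <- scenario_spec("A", c(7, 23), Inf)
  res <- run_psa(w$cohort, w$region, sc, model_config(),
                 n_iterations = 8, n_runs = 2, seed = 4)
  d <- withr::local_tempdir()
  traj <- evaluate_strategies(w$cohort, w$region, sc, model_config(),
                              seed = 4, by_year = TRUE)$by_year
  files <- export_results(res, d, trajectory = traj)
  expect_true(all(file.exists(file.path(
    d, c("results_table.csv", "psa_draws.csv", "scatter.csv",
         "summary.json", "inmb_trajectory.csv")))))
  # scatter has one row per iteration x run
  sc_df <- utils::read.csv(file.path(d, "scatter.csv"))
  expect_equal(nrow(sc_df), 8 * 2)
  # results table has one row per scenario with the documented columns
  tab <- utils::read.csv(file.path(d, "results_table.csv"))
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("n_dispatches", "availability", "delta_qaly_mean",
                    "cost_savings_mean", "inmb_mean") %in% names(tab)))
  # JSON read-back matches the in-memory table
  js <- jsonlite::read_json(file.path(d, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$table$inmb_mean,
               res$summary$mean[res$summary$quantity == "inmb"],
               tolerance = 1e-9)
})

test_that("out-of-bound parameter draws are redrawn inside bounds", {
  set.seed(1)
  pd <- param_dist("x", c("outcome", "beta_ivt"), "normal",
                   list(mean = 0, sd = 1), bounds = c(0, Inf))
  draws <- replicate(200, msucea:::draw_one(pd))
  expect_true(all(draws >= 0))
})
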