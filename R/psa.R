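# Probabilistic sensitivity analysis, one-way tornado analysis, and the
# dispatch scenario grid.

#' Define a parameter distribution for the PSA
#'
#' Distribution families follow standard health-economic practice: beta for
#' probabilities and utilities, gamma for costs and times, normal for
#' log-odds treatment effects. Parameters may be vectors (e.g. one utility
#' per mRS state); the draw is then element-wise.
#'
#' @param name unique parameter name
#' @param path character vector addressing the value inside a
#'   [model_config()] (e.g. `c("outcome", "beta_ivt")`)
#' @param kind one of `beta`, `gamma`, `normal`, `lognormal`, `uniform`,
#'   `fixed`
#' @param pars named list: beta takes `mean` and `kappa` (concentration,
#'   shape1 = mean x kappa); gamma takes `mean` and `cv`; normal takes
#'   `mean` and `sd`; lognormal takes `meanlog` and `sdlog`; uniform takes
#'   `min` and `max`; fixed takes `value`
#' @param bounds length-2 allowed interval; out-of-bound draws are redrawn
#'   (with a warning and clamping after 100 rejections)
#' @return a `param_dist` list
#' @export
param_dist <- function(name, path, kind, pars, bounds = c(-Inf, Inf)) {
  kind <- match.arg(kind, c("beta", "gamma", "normal", "lognormal",
                            "uniform", "fixed"))
  structure(list(name = name, path = path, kind = kind, pars = pars,
                 bounds = bounds), class = "param_dist")
}

draw_one <- function(pd) {
  p <- pd$pars
  draw <- switch(pd$kind,
    fixed = return(p$value),
    beta = function() stats::rbeta(length(p$mean), p$mean * p$kappa,
                                   (1 - p$mean) * p$kappa),
    gamma = function() {
      shape <- 1 / p$cv^2
      stats::rgamma(length(p$mean), shape = shape, rate = shape / p$mean)
    },
    normal = function() stats::rnorm(length(p$mean), p$mean, p$sd),
    lognormal = function() stats::rlnorm(length(p$meanlog), p$meanlog,
                                         p$sdlog),
    uniform = function() stats::runif(length(p$min), p$min, p$max))
  x <- draw()
  tries <- 0
  while (any(x < pd$bounds[1] | x > pd$bounds[2])) {
    tries <- tries + 1
    if (tries > 100) {
      warning("parameter '", pd$name,
              "': 100 out-of-bound redraws, clamping to bounds")
      x <- pmin(pmax(x, pd$bounds[1]), pd$bounds[2])
      break
    }
    bad <- x < pd$bounds[1] | x > pd$bounds[2]
    x[bad] <- draw()[bad]
  }
  x
}

assign_path <- function(config, path, value) {
  config[[path]] <- value
  config
}

# draw every PSA parameter once and substitute into the configuration
draw_psa_config <- function(config, psa) {
  for (pd in psa) {
    config <- assign_path(config, pd$path, draw_one(pd))
  }
  # joint guard: diagnosis probabilities must leave room for ischemic stroke
  epi <- config$epi
  s <- epi$p_mimic + epi$p_tia + epi$p_ich
  if (s > 0.99) {
    f <- 0.99 / s
    config$epi$p_mimic <- epi$p_mimic * f
    config$epi$p_tia <- epi$p_tia * f
    config$epi$p_ich <- epi$p_ich * f
  }
  config
}

#' Default PSA distribution set
#'
#' Covers the parameters the model is most sensitive to: diagnosis-mix
#' probabilities, treatment-receipt probabilities (beta), treatment effects
#' and their per-minute decay (normal, decay bounded above by 0), utilities
#' per mRS state (beta), long-term annual costs per state and key acute
#' costs (gamma). Mortality, travel times and discount rates are held fixed
#' by default.
#'
#' @param config the [model_config()] whose base values center the
#'   distributions
#' @return list of [param_dist()] objects
#' @export
default_psa <- function(config = model_config()) {
  om <- config$outcome; epi <- config$epi; ec <- config$econ
  list(
    param_dist("p_mimic", c("epi", "p_mimic"), "beta",
               list(mean = epi$p_mimic, kappa = 200), c(0, 1)),
    param_dist("p_tia", c("epi", "p_tia"), "beta",
               list(mean = epi$p_tia, kappa = 200), c(0, 1)),
    param_dist("p_ich", c("epi", "p_ich"), "beta",
               list(mean = epi$p_ich, kappa = 200), c(0, 1)),
    param_dist("p_lvo_given_ischemic", c("epi", "p_lvo_given_ischemic"),
               "beta", list(mean = epi$p_lvo_given_ischemic, kappa = 150),
               c(0, 1)),
    param_dist("p_ivt_given_eligible",
               c("outcome", "p_ivt_given_eligible"), "beta",
               list(mean = om$p_ivt_given_eligible, kappa = 100), c(0, 1)),
    param_dist("p_evt_given_lvo_eligible",
               c("outcome", "p_evt_given_lvo_eligible"), "beta",
               list(mean = om$p_evt_given_lvo_eligible, kappa = 100),
               c(0, 1)),
    param_dist("beta_ivt", c("outcome", "beta_ivt"), "normal",
               list(mean = om$beta_ivt, sd = 0.1 * abs(om$beta_ivt)),
               c(0, Inf)),
    param_dist("beta_evt", c("outcome", "beta_evt"), "normal",
               list(mean = om$beta_evt, sd = 0.1 * abs(om$beta_evt)),
               c(0, Inf)),
    param_dist("beta_ivt_decay", c("outcome", "beta_ivt_decay"), "normal",
               list(mean = om$beta_ivt_decay,
                    sd = 0.15 * abs(om$beta_ivt_decay)), c(-Inf, 0)),
    param_dist("beta_evt_decay", c("outcome", "beta_evt_decay"), "normal",
               list(mean = om$beta_evt_decay,
                    sd = 0.15 * abs(om$beta_evt_decay)), c(-Inf, 0)),
    param_dist("utility_by_mrs", c("econ", "utility_by_mrs"), "beta",
               list(mean = ec$utility_by_mrs, kappa = 100), c(0, 1)),
    param_dist("annual_cost_by_mrs", c("econ", "annual_cost_by_mrs"),
               "gamma", list(mean = ec$annual_cost_by_mrs, cv = 0.15),
               c(0, Inf)),
    param_dist("msu_ride_cost", c("econ", "acute_costs", "msu_ride"),
               "gamma", list(mean = ec$acute_costs$msu_ride, cv = 0.2),
               c(0, Inf)))
}

# does any PSA parameter touch a block that would invalidate the prepared
# evaluation context (times, dispatch) or the annuity factors?
psa_touches <- function(psa, block) {
  any(vapply(psa, function(pd) pd$path[1] == block, logical(1)))
}

#' Run the probabilistic sensitivity analysis for one scenario
#'
#' Per iteration one parameter set is drawn and both strategies are
#' evaluated on the fixed cohort with common random numbers; the deltas and
#' the iNMB are recorded. Iterations are organised in `n_runs` separate
#' runs (each run re-seeds the patient-level draws); reported means average
#' over all draws and 95% intervals are the 2.5/97.5 percentiles of the
#' pooled draws. Everything is deterministic given the seed.
#'
#' @param cohort a `msu_cohort`
#' @param region a `msu_region`
#' @param scenario a [scenario_spec()]
#' @param config a [model_config()]
#' @param psa list of [param_dist()] (default [default_psa()]); use
#'   `list()` for a fully deterministic evaluation
#' @param n_iterations iterations per run
#' @param n_runs number of runs averaged
#' @param seed master seed; run and iteration seeds derive from it
#' @return a `scenario_result` list: `draws` (one row per iteration),
#'   `summary` (means and 95% intervals for delta QALY, delta cost, iNMB),
#'   dispatch statistics and the scenario
#' @export
run_psa <- function(cohort, region, scenario, config = model_config(),
                    psa = default_psa(config), n_iterations = 3000,
                    n_runs = 10, seed = 1L) {
  if (n_iterations < 1 || n_runs < 1) stop("need >= 1 iteration and run")
  redo_ctx <- psa_touches(psa, "times")
  redo_ann <- psa_touches(psa, "mortality")
  draws <- vector("list", n_runs)
  disp_stats <- NULL
  for (r in seq_len(n_runs)) {
    run_seed <- (seed + 104729 * r) %% 2147483647
    ctx <- prepare_evaluation(cohort, region, scenario, config, run_seed)
    if (is.null(disp_stats)) disp_stats <- ctx$dispatch
    set.seed((run_seed + 1) %% 2147483647)
    rows <- matrix(NA_real_, n_iterations, 3)
    for (it in seq_len(n_iterations)) {
      cfg_it <- draw_psa_config(config, psa)
      if (redo_ctx) {
        ctx <- prepare_evaluation(cohort, region, scenario, cfg_it, run_seed)
      } else if (redo_ann) {
        ctx$ann_e <- annuity_factors(cfg_it$mortality,
                                     cfg_it$econ$discount_effects)
        ctx$ann_c <- annuity_factors(cfg_it$mortality,
                                     cfg_it$econ$discount_costs)
      }
      res <- evaluate_with_params(ctx, cfg_it)
      rows[it, ] <- c(res$delta_qaly, res$delta_cost, res$inmb)
    }
    draws[[r]] <- data.frame(run = r, iteration = seq_len(n_iterations),
                             delta_qaly = rows[, 1], delta_cost = rows[, 2],
                             inmb = rows[, 3])
  }
  draws <- do.call(rbind, draws)
  ci <- function(x) unname(stats::quantile(x, c(0.025, 0.975)))
  summary <- data.frame(
    quantity = c("delta_qaly", "delta_cost", "inmb"),
    mean = c(mean(draws$delta_qaly), mean(draws$delta_cost),
             mean(draws$inmb)),
    lo95 = c(ci(draws$delta_qaly)[1], ci(draws$delta_cost)[1],
             ci(draws$inmb)[1]),
    hi95 = c(ci(draws$delta_qaly)[2], ci(draws$delta_cost)[2],
             ci(draws$inmb)[2]),
    stringsAsFactors = FALSE)
  structure(list(scenario = scenario, draws = draws, summary = summary,
                 n_dispatches = disp_stats$n_dispatched,
                 availability_fraction = disp_stats$availability_fraction,
                 n_eligible = disp_stats$n_eligible,
                 n_eligible_in_catchment = disp_stats$n_eligible_in_catchment,
                 n_iterations = n_iterations, n_runs = n_runs, seed = seed),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  fmt <- function(row, scale = 1, digits = 1) {
    sprintf("%.*f (%.*f to %.*f)", digits, row$mean / scale, digits,
            row$lo95 / scale, digits, row$hi95 / scale)
  }
  cat("Scenario:", x$scenario$msu_site_id,
      sprintf("%02d:00-%02d:00", x$scenario$window_hours[1],
              x$scenario$window_hours[2]),
      if (is.infinite(x$scenario$catchment_min)) "entire region"
      else paste0(x$scenario$catchment_min, "-min catchment"), "\n")
  cat("  MSU dispatches:", x$n_dispatches,
      sprintf("(availability %.1f%%)", 100 * x$availability_fraction), "\n")
  cat("  delta QALY:", fmt(s[s$quantity == "delta_qaly", ]), "\n")
  cat("  delta cost (EUR million):",
      fmt(s[s$quantity == "delta_cost", ], 1e6, 2), "\n")
  cat("  iNMB (EUR million):", fmt(s[s$quantity == "inmb", ], 1e6, 2), "\n")
  invisible(x)
}

#' Run a grid of dispatch scenarios
#'
#' One PSA per combination of dispatch site, daily operating window and
#' catchment limit. All scenarios share the master seed so patient-level
#' draws and parameter draws are identical across scenarios, making the
#' EMS-alone comparator effectively shared.
#'
#' @param cohort,region,config,psa,n_iterations,n_runs,seed as in
#'   [run_psa()]
#' @param sites dispatch site ids
#' @param windows list of `c(start, end)` daily windows in clock hours
#' @param catchments catchment limits in minutes (`Inf` = entire region)
#' @return a `scenario_grid` list: `results` (per-scenario
#'   `scenario_result`s) and `table` (one row per scenario in a
#'   results-table schema)
#' @export
run_scenario_grid <- function(cohort, region, config = model_config(),
                              sites = "A",
                              windows = list(c(9, 21), c(7, 23), c(0, 24)),
                              catchments = c(Inf, 25, 20, 15),
                              psa = default_psa(config),
                              n_iterations = 3000, n_runs = 10, seed = 1L) {
  grid <- expand.grid(site = sites, w = seq_along(windows),
                      catchment = catchments, stringsAsFactors = FALSE)
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- scenario_spec(msu_site_id = grid$site[i],
                        window_hours = windows[[grid$w[i]]],
                        catchment_min = grid$catchment[i])
    results[[i]] <- run_psa(cohort, region, sc, config, psa,
                            n_iterations, n_runs, seed)
  }
  structure(list(results = results, table = grid_table(results)),
            class = "scenario_grid")
}

# Results-table schema: one row per scenario with dispatch counts,
# availability, and mean (95% interval) gain in QALYs, cost savings and
# iNMB.
grid_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    s <- r$summary
    g <- function(q, f) s[s$quantity == q, f]
    data.frame(
      site = r$scenario$msu_site_id,
      window = sprintf("%02d:00-%02d:00", r$scenario$window_hours[1],
                       r$scenario$window_hours[2]),
      catchment_min = r$scenario$catchment_min,
      n_dispatches = r$n_dispatches,
      availability = r$availability_fraction,
      delta_qaly_mean = g("delta_qaly", "mean"),
      delta_qaly_lo95 = g("delta_qaly", "lo95"),
      delta_qaly_hi95 = g("delta_qaly", "hi95"),
      cost_savings_mean = -g("delta_cost", "mean"),
      cost_savings_lo95 = -g("delta_cost", "hi95"),
      cost_savings_hi95 = -g("delta_cost", "lo95"),
      inmb_mean = g("inmb", "mean"),
      inmb_lo95 = g("inmb", "lo95"),
      inmb_hi95 = g("inmb", "hi95"),
      stringsAsFactors = FALSE)
  }))
}

#' One-way (tornado) sensitivity analysis
#'
#' Each listed parameter is set to its low and high value in turn with all
#' other parameters at base values, and the model is evaluated
#' deterministically (no PSA draws). Rows are ordered by the iNMB swing.
#'
#' @param cohort,region,scenario,config,seed as in [evaluate_strategies()]
#' @param ranges named list; each element is
#'   `list(path = c(...), low = value, high = value)`
#' @return data.frame with per-strategy totals and deltas at the low and
#'   high setting of every parameter, ordered by decreasing `|swing_inmb|`
#' @export
tornado <- function(cohort, region, scenario, config = model_config(),
                    ranges = default_tornado_ranges(config), seed = 1L) {
  if (anyDuplicated(names(ranges))) {
    stop("duplicate parameter names in tornado ranges")
  }
  ctx <- prepare_evaluation(cohort, region, scenario, config, seed)
  eval_at <- function(cfg) evaluate_with_params(ctx, cfg)
  rows <- lapply(names(ranges), function(nm) {
    rg <- ranges[[nm]]
    lo <- eval_at(assign_path(config, rg$path, rg$low))
    hi <- eval_at(assign_path(config, rg$path, rg$high))
    data.frame(parameter = nm, low = rg$low, high = rg$high,
               qaly_msu_low = lo$qaly_msu, qaly_msu_high = hi$qaly_msu,
               qaly_ems_low = lo$qaly_ems, qaly_ems_high = hi$qaly_ems,
               cost_msu_low = lo$cost_msu, cost_msu_high = hi$cost_msu,
               cost_ems_low = lo$cost_ems, cost_ems_high = hi$cost_ems,
               delta_qaly_low = lo$delta_qaly,
               delta_qaly_high = hi$delta_qaly,
               delta_cost_low = lo$delta_cost,
               delta_cost_high = hi$delta_cost,
               inmb_low = lo$inmb, inmb_high = hi$inmb,
               swing_inmb = abs(hi$inmb - lo$inmb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing_inmb), ]
  rownames(out) <- NULL
  out
}

#' Default tornado ranges
#'
#' Plausibility ranges for the most influential parameters, centered on the
#' base configuration.
#'
#' @param config a [model_config()]
#' @return named list of `list(path, low, high)` entries
#' @export
default_tornado_ranges <- function(config = model_config()) {
  epi <- config$epi; om <- config$outcome; ec <- config$econ
  list(
    p_mimic = list(path = c("epi", "p_mimic"),
                   low = 0.8 * epi$p_mimic, high = 1.2 * epi$p_mimic),
    p_tia = list(path = c("epi", "p_tia"),
                 low = 0.8 * epi$p_tia, high = 1.2 * epi$p_tia),
    p_ich = list(path = c("epi", "p_ich"),
                 low = 0.8 * epi$p_ich, high = 1.2 * epi$p_ich),
    p_lvo_given_ischemic = list(path = c("epi", "p_lvo_given_ischemic"),
                                low = 0.8 * epi$p_lvo_given_ischemic,
                                high = 1.2 * epi$p_lvo_given_ischemic),
    beta_ivt = list(path = c("outcome", "beta_ivt"),
                    low = 0.8 * om$beta_ivt, high = 1.2 * om$beta_ivt),
    beta_evt = list(path = c("outcome", "beta_evt"),
                    low = 0.8 * om$beta_evt, high = 1.2 * om$beta_evt),
    msu_ride_cost = list(path = c("econ", "acute_costs", "msu_ride"),
                         low = 0.5 * ec$acute_costs$msu_ride,
                         high = 1.5 * ec$acute_costs$msu_ride),
    msu_personnel = list(path = c("econ", "msu_program", "personnel_annual"),
                         low = 0.8 * ec$msu_program$personnel_annual,
                         high = 1.2 * ec$msu_program$personnel_annual))
}

#' Export analysis results to files
#'
#' Writes a results-table CSV (one row per scenario), the pooled PSA draws,
#' a cost-effectiveness scatter file (delta cost vs delta QALY per
#' iteration), a machine-readable JSON summary, and, when a trajectory is
#' supplied, the cumulative-iNMB-by-year table.
#'
#' @param x a `scenario_result` or `scenario_grid`
#' @param dir output directory (created if needed)
#' @param trajectory optional `by_year` data.frame from
#'   [evaluate_strategies()]
#' @return invisible character vector of files written
#' @export
export_results <- function(x, dir, trajectory = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  results <- if (inherits(x, "scenario_grid")) x$results else list(x)
  tab <- grid_table(results)
  files <- character(0)
  f <- file.path(dir, "results_table.csv")
  utils::write.csv(tab, f, row.names = FALSE); files <- c(files, f)
  draws <- do.call(rbind, lapply(seq_along(results), function(i) {
    cbind(scenario = i, results[[i]]$draws)
  }))
  f <- file.path(dir, "psa_draws.csv")
  utils::write.csv(draws, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "scatter.csv")
  utils::write.csv(draws[, c("scenario", "delta_qaly", "delta_cost")], f,
                   row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(table = tab,
         settings = list(n_iterations = results[[1]]$n_iterations,
                         n_runs = results[[1]]$n_runs,
                         seed = results[[1]]$seed)),
    f, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, f)
  if (!is.null(trajectory)) {
    f <- file.path(dir, "inmb_trajectory.csv")
    utils::write.csv(trajectory, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
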