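# Strategy evaluation engine: runs the fixed virtual cohort through the
# MSU+EMS and EMS-alone arms with common random numbers and accrues
# per-patient lifetime values.

#' Model configuration
#'
#' Bundles all parameter blocks of the model. Each block has its own
#' constructor with documented defaults; the configuration is what the
#' probabilistic sensitivity analysis perturbs.
#'
#' @param epi [epidemiology_params()]
#' @param times [time_params()]
#' @param outcome [outcome_model()]
#' @param econ [economic_params()]
#' @param mortality [mortality_params()]
#' @param horizon_years MSU implementation horizon (program costs scale
#'   with it; the cohort is one year of alarms)
#' @return a `model_config` list
#' @export
model_config <- function(epi = epidemiology_params(), times = time_params(),
                         outcome = outcome_model(),
                         econ = economic_params(),
                         mortality = mortality_params(),
                         horizon_years = 1) {
  structure(list(epi = epi, times = times, outcome = outcome, econ = econ,
                 mortality = mortality, horizon_years = horizon_years),
            class = "model_config")
}

# Fixed per-(cohort, region, scenario, seed) context reused across
# parameter draws: eligible patients in alarm order, their common random
# numbers, the dispatch log, and both arms' pathway times computed "as if
# LVO" so that per-draw diagnosis reassignment only has to mask rows.
# ott_ivt does not depend on the LVO flag (the thrombolysis pathway is the
# same), and ott_evt is only read for patients whose drawn diagnosis is
# LVO, so the as-if-LVO breakdown carries every quantity any draw needs.
prepare_evaluation <- function(cohort, region, scenario, config, seed) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  elig <- elig[order(elig$alarm_time_min, elig$patient_id), , drop = FALSE]
  rownames(elig) <- NULL
  n <- nrow(elig)
  crn <- draw_crn(n, seed)

  disp <- simulate_availability(elig, region, scenario, config$times,
                                seed = seed)
  dispatched <- disp$log$msu_dispatched[match(elig$patient_id,
                                              disp$log$patient_id)]

  has_tsc <- any(as.logical(region$hospitals$tsc))
  aslvo <- elig
  if (has_tsc) aslvo$diagnosis <- "ischemic_lvo"
  class(aslvo) <- class(elig)
  bd_msu <- compute_pathway_times(aslvo, dispatched, region, scenario,
                                  config$times, crn)
  bd_ems <- compute_pathway_times(aslvo, rep(FALSE, n), region, scenario,
                                  config$times, crn)

  list(elig = elig, crn = crn, dispatch = disp, dispatched = dispatched,
       bd_msu = bd_msu, bd_ems = bd_ems, has_tsc = has_tsc,
       scenario = scenario,
       ann_e = annuity_factors(config$mortality,
                               config$econ$discount_effects),
       ann_c = annuity_factors(config$mortality, config$econ$discount_costs))
}

# vectorised proportional-odds shift: one base distribution, a vector of
# deltas; returns the n x 6 cumulative matrix P(mRS <= k)
shift_cumulative <- function(base, delta) {
  cum <- pmin(pmax(cumsum(base[1:6]), 1e-12), 1 - 1e-12)
  lg <- stats::qlogis(cum)
  stats::plogis(outer(delta, rep(1, 6)) + matrix(lg, length(delta), 6,
                                                 byrow = TRUE))
}

# One strategy arm: treatment receipt, 90-day state, lifetime values and
# acute costs for every eligible patient, given the current parameter set.
evaluate_arm <- function(ctx, config, bd, dispatched, diagnosis, lk) {
  elig <- ctx$elig; crn <- ctx$crn; om <- config$outcome
  n <- nrow(elig)
  lvo <- diagnosis == "ischemic_lvo"
  nonlvo <- diagnosis == "ischemic_nonlvo"
  ischemic <- lvo | nonlvo
  if (any(lvo) && !ctx$has_tsc) {
    stop("LVO pathway requires at least one thrombectomy-capable center")
  }

  ivt_taker <- crn$u_ivt < om$p_ivt_given_eligible
  evt_taker <- crn$u_evt < om$p_evt_given_lvo_eligible
  treated_ivt <- ischemic & ivt_taker & bd$ott_ivt < om$ivt_window
  treated_evt <- lvo & evt_taker & !is.na(bd$ott_evt) &
    bd$ott_evt < om$evt_window

  d_ivt <- ifelse(treated_ivt,
                  treatment_delta(om$beta_ivt, om$beta_ivt_decay,
                                  pmax(bd$ott_ivt, 0), om$ivt_window), 0)
  d_evt <- ifelse(treated_evt,
                  treatment_delta(om$beta_evt, om$beta_evt_decay,
                                  pmax(ifelse(is.na(bd$ott_evt), 0,
                                              bd$ott_evt), 0),
                                  om$evt_window), 0)
  delta <- if (om$additive_lvo_effects) d_ivt + d_evt else pmax(d_ivt, d_evt)

  # 90-day state index into c(mrs0..mrs6, nonstroke)
  state <- integer(n)
  u <- crn$u_mrs
  state[diagnosis == "mimic"] <- 8L
  state[diagnosis == "tia"] <- 1L
  ich <- diagnosis == "ich"
  if (any(ich)) {
    cum_ich <- cumsum(om$mrs_ich[1:6])
    state[ich] <- 1L + findInterval(u[ich], cum_ich)
  }
  if (any(nonlvo)) {
    cum <- shift_cumulative(om$mrs_untreated_nonlvo, delta[nonlvo])
    state[nonlvo] <- 1L + rowSums(u[nonlvo] > cum)
  }
  if (any(lvo)) {
    cum <- shift_cumulative(om$mrs_untreated_lvo, delta[lvo])
    state[lvo] <- 1L + rowSums(u[lvo] > cum)
  }

  age_idx <- pmin(pmax(floor(elig$age), 0), 110) + 1L
  qaly <- lk$qaly[cbind(age_idx, state)]
  cost_lt <- lk$cost[cbind(age_idx, state)]
  # via-PSC routing applies to LVO patients without MSU dispatch whose
  # nearest center is primary (the as-if-LVO breakdown labels those rows)
  routing <- ifelse(lvo, bd$routing, "ems_to_psc")
  cost_acute <- acute_cost(dispatched, treated_ivt, treated_evt, routing,
                           config$econ)
  list(treated_ivt = treated_ivt, treated_evt = treated_evt,
       state = state, qaly = qaly, cost_lt = cost_lt,
       cost_acute = cost_acute, routing = routing,
       qaly_by_year = lk$qaly_by_year, cost_by_year = lk$cost_by_year,
       age_idx = age_idx)
}

# Evaluate both strategies under the current parameter set using the
# prepared context. Returns strategy totals, deltas and the iNMB.
evaluate_with_params <- function(ctx, config, by_year = FALSE,
                                 per_patient = FALSE) {
  elig <- ctx$elig
  n <- nrow(elig)
  epi <- config$epi
  diagnosis <- if (n) assign_diagnosis(elig$u_diag, epi) else character(0)

  lk <- lifetime_lookup(config$econ, config$mortality,
                        ann_e = ctx$ann_e, ann_c = ctx$ann_c)
  msu <- evaluate_arm(ctx, config, ctx$bd_msu, ctx$dispatched, diagnosis, lk)
  ems <- evaluate_arm(ctx, config, ctx$bd_ems, rep(FALSE, n), diagnosis, lk)

  prog <- program_cost(config$econ, config$horizon_years)
  qaly_msu <- sum(msu$qaly); qaly_ems <- sum(ems$qaly)
  cost_msu <- sum(msu$cost_lt) + sum(msu$cost_acute) + prog
  cost_ems <- sum(ems$cost_lt) + sum(ems$cost_acute)
  delta_qaly <- qaly_msu - qaly_ems
  delta_cost <- cost_msu - cost_ems

  out <- list(
    n_eligible = n,
    n_dispatched = ctx$dispatch$n_dispatched,
    availability_fraction = ctx$dispatch$availability_fraction,
    n_eligible_in_catchment = ctx$dispatch$n_eligible_in_catchment,
    qaly_msu = qaly_msu, qaly_ems = qaly_ems,
    cost_msu = cost_msu, cost_ems = cost_ems,
    program_cost = prog,
    delta_qaly = delta_qaly, delta_cost = delta_cost,
    inmb = inmb(delta_qaly, delta_cost, config$econ$wtp),
    n_transfers_avoided = sum(diagnosis == "ischemic_lvo" &
                                ctx$dispatched &
                                ctx$bd_ems$routing == "ems_via_psc"))
  if (per_patient) {
    out$per_patient <- data.frame(
      patient_id = elig$patient_id, age = elig$age,
      diagnosis = diagnosis, msu_dispatched = ctx$dispatched,
      treated_ivt_msu = msu$treated_ivt, treated_evt_msu = msu$treated_evt,
      treated_ivt_ems = ems$treated_ivt, treated_evt_ems = ems$treated_evt,
      ott_ivt_msu = ctx$bd_msu$ott_ivt, ott_ivt_ems = ctx$bd_ems$ott_ivt,
      ott_evt_msu = ctx$bd_msu$ott_evt, ott_evt_ems = ctx$bd_ems$ott_evt,
      mrs90_msu = c(0:6, NA)[msu$state], mrs90_ems = c(0:6, NA)[ems$state],
      qaly_msu = msu$qaly, qaly_ems = ems$qaly,
      cost_msu = msu$cost_lt + msu$cost_acute,
      cost_ems = ems$cost_lt + ems$cost_acute,
      stringsAsFactors = FALSE)
    out$diagnosis <- diagnosis
  }
  if (by_year) {
    yrs <- dim(msu$qaly_by_year)[3]
    dq <- dc <- numeric(yrs)
    for (y in seq_len(yrs)) {
      dq[y] <- sum(msu$qaly_by_year[cbind(msu$age_idx, msu$state, y)]) -
        sum(ems$qaly_by_year[cbind(ems$age_idx, ems$state, y)])
      dc[y] <- sum(msu$cost_by_year[cbind(msu$age_idx, msu$state, y)]) -
        sum(ems$cost_by_year[cbind(ems$age_idx, ems$state, y)])
    }
    dc[1] <- dc[1] + sum(msu$cost_acute) - sum(ems$cost_acute) + prog
    out$by_year <- data.frame(
      year = seq_len(yrs), delta_qaly = dq, delta_cost = dc,
      cum_inmb = cumsum(dq * config$econ$wtp - dc))
  }
  out
}

#' Evaluate the MSU+EMS and EMS-alone strategies on a cohort
#'
#' Runs every eligible patient through both strategy arms with common
#' random numbers: the same patient shares the onset-to-alarm time,
#' travel/on-scene noise, treatment-taker draws, and the uniform behind the
#' 90-day state draw in both arms, so differences are driven by the MSU's
#' effect on treatment times and routing alone. Lifetime values use the
#' closed-form expected accrual conditional on the drawn 90-day state.
#'
#' @param cohort a `msu_cohort`
#' @param region a `msu_region`
#' @param scenario a [scenario_spec()]
#' @param config a [model_config()]
#' @param seed RNG seed for patient-level draws
#' @param by_year also return the year-by-year delta trajectory
#' @param per_patient also return the per-patient log
#' @return list with strategy totals (`qaly_msu`, `cost_msu`, ...), deltas,
#'   `inmb`, dispatch statistics, and optionally `by_year` / `per_patient`
#' @export
evaluate_strategies <- function(cohort, region, scenario,
                                config = model_config(), seed = 1L,
                                by_year = FALSE, per_patient = FALSE) {
  ctx <- prepare_evaluation(cohort, region, scenario, config, seed)
  evaluate_with_params(ctx, config, by_year = by_year,
                       per_patient = per_patient)
}

#' Incremental net monetary benefit
#'
#' `iNMB = delta_QALY x WTP - delta_cost`, with `delta_cost` the MSU+EMS
#' cost minus the EMS-alone cost, so cost savings increase the iNMB.
#'
#' @param delta_qaly QALY gain of MSU+EMS over EMS alone
#' @param delta_cost cost difference (MSU+EMS minus EMS alone), euros
#' @param wtp willingness-to-pay threshold (euros per QALY)
#' @return euros
#' @export
inmb <- function(delta_qaly, delta_cost, wtp = 50000) {
  delta_qaly * wtp - delta_cost
}
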