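# Lifetime accrual of discounted QALYs and costs from the 90-day health
# state, plus acute-phase and MSU program costs.

#' Economic parameters
#'
#' Utility weights and annual long-term care costs per health state, acute
#' care unit costs, MSU program costs, discount rates, and the
#' willingness-to-pay threshold. Long-term costs rise steeply with
#' disability (institutionalised care in mRS 4--5); the non-stroke state
#' (mimics) carries near-normal utility and low cost. Default monetary
#' values are stand-ins in 2021--2022 euros, not authoritative estimates;
#' discount rates (1.5% effects, 4.0% costs) follow Dutch guidance for
#' health-economic evaluation, and the willingness-to-pay threshold is
#' EUR 50,000 per QALY.
#'
#' @param utility_by_mrs utility weight per mRS 0--5 (mRS 6 is 0)
#' @param utility_nonstroke utility of the non-stroke state
#' @param annual_cost_by_mrs long-term cost (EUR/year) per mRS 0--5
#' @param annual_cost_nonstroke long-term cost of the non-stroke state
#' @param acute_costs named list: `ems_ride`, `msu_ride`, `ivt`, `evt`,
#'   `ed_visit_deduction` (emergency-department cost saved when the patient
#'   is treated in the MSU), `interhospital_transfer`
#' @param msu_program named list: `investment_total` (depreciated over
#'   `depreciation_years`), `operational_annual`, `personnel_annual`
#' @param discount_effects,discount_costs annual discount rates
#' @param wtp willingness-to-pay threshold (EUR per QALY)
#' @return an `economic_params` list
#' @export
economic_params <- function(
    utility_by_mrs = c(0.95, 0.93, 0.83, 0.62, 0.42, 0.11),
    utility_nonstroke = 0.95,
    annual_cost_by_mrs = c(1500, 3500, 7000, 18000, 38000, 46000),
    annual_cost_nonstroke = 1200,
    acute_costs = list(ems_ride = 700, msu_ride = 1800, ivt = 950,
                       evt = 9800, ed_visit_deduction = 400,
                       interhospital_transfer = 750),
    msu_program = list(investment_total = 1e6, depreciation_years = 5,
                       operational_annual = 250000,
                       personnel_annual = 650000),
    discount_effects = 0.015, discount_costs = 0.04, wtp = 50000) {
  u <- c(utility_by_mrs, utility_nonstroke)
  if (length(utility_by_mrs) != 6 || any(u < -0.2 | u > 1)) {
    stop("utilities must be 6 values (mRS 0-5) in [-0.2, 1]")
  }
  if (length(annual_cost_by_mrs) != 6 || any(annual_cost_by_mrs < 0)) {
    stop("annual_cost_by_mrs must be 6 non-negative values")
  }
  if (discount_effects < 0 || discount_effects >= 1 ||
      discount_costs < 0 || discount_costs >= 1) {
    stop("discount rates must be in [0, 1)")
  }
  if (msu_program$depreciation_years <= 0) {
    stop("depreciation_years must be > 0")
  }
  need <- c("ems_ride", "msu_ride", "ivt", "evt", "ed_visit_deduction",
            "interhospital_transfer")
  if (!all(need %in% names(acute_costs))) {
    stop("acute_costs missing: ",
         paste(setdiff(need, names(acute_costs)), collapse = ", "))
  }
  structure(list(utility_by_mrs = utility_by_mrs,
                 utility_nonstroke = utility_nonstroke,
                 annual_cost_by_mrs = annual_cost_by_mrs,
                 annual_cost_nonstroke = annual_cost_nonstroke,
                 acute_costs = acute_costs, msu_program = msu_program,
                 discount_effects = discount_effects,
                 discount_costs = discount_costs, wtp = wtp),
            class = "economic_params")
}

#' Mortality parameters
#'
#' All-cause annual mortality by single year of age plus death hazard rate
#' ratios per mRS category. The default age table is a Gompertz-Makeham
#' approximation of a contemporary west-European life table; the hazard
#' ratios rise with disability. Values are stand-ins, not authoritative.
#'
#' @param annual_mortality_by_age probability of death within a year, one
#'   value per age `0..(length-1)`; beyond the table death is certain
#' @param hr_by_mrs hazard rate ratio per mRS 0--5 (applied on the hazard
#'   scale)
#' @param hr_nonstroke hazard ratio of the non-stroke state
#' @param max_cycles number of model cycles after which all patients are
#'   assumed dead
#' @return a `mortality_params` list
#' @export
mortality_params <- function(
    annual_mortality_by_age = 1 - exp(-(8e-05 + exp(-10.2 + 0.097 * (0:110)))),
    hr_by_mrs = c(1.0, 1.2, 1.6, 2.3, 3.4, 5.0),
    hr_nonstroke = 1.0,
    max_cycles = 100L) {
  q <- annual_mortality_by_age
  if (any(q < 0 | q > 1)) stop("annual mortality must be probabilities")
  if (length(hr_by_mrs) != 6 || any(hr_by_mrs <= 0)) {
    stop("hr_by_mrs must be 6 positive hazard ratios")
  }
  if (max_cycles < 2) stop("max_cycles must be >= 2")
  structure(list(annual_mortality_by_age = q, hr_by_mrs = hr_by_mrs,
                 hr_nonstroke = hr_nonstroke,
                 max_cycles = as.integer(max_cycles)),
            class = "mortality_params")
}

# baseline annual death hazard at integer age; beyond the table the hazard
# is infinite (death within the cycle is certain)
base_hazard <- function(age, mortality) {
  q <- mortality$annual_mortality_by_age
  out <- rep(Inf, length(age))
  inside <- age >= 0 & age < length(q)
  out[inside] <- -log(1 - q[age[inside] + 1])
  out
}

state_hr <- function(state, mortality) {
  ifelse(state == NONSTROKE_STATE, mortality$hr_nonstroke,
         ifelse(state == "mrs6", Inf,
                mortality$hr_by_mrs[match(state, MRS_STATES)]))
}

#' Annual survival probability given age and health state
#'
#' The mRS-specific hazard ratio is applied on the hazard scale: the annual
#' probability of death is `1 - exp(-HR * (-log(1 - q_age)))`, i.e.
#' `1 - (1 - q_age)^HR`, and the survival probability is its complement.
#' Ages beyond the mortality table have death probability 1.
#'
#' @param age integer age in years (>= 0)
#' @param mrs mRS state 0--5, or `"nonstroke"`
#' @param mortality [mortality_params()]
#' @return annual survival probability
#' @export
survival_probability <- function(age, mrs, mortality = mortality_params()) {
  if (any(age < 0)) stop("age must be >= 0")
  state <- if (is.numeric(mrs)) {
    if (any(mrs < 0 | mrs > 5)) stop("mrs must be in 0..5 (or 'nonstroke')")
    MRS_STATES[mrs + 1]
  } else mrs
  hr <- state_hr(state, mortality)
  exp(-hr * base_hazard(age, mortality))
}

# Cycle grid: the first cycle covers the 90 days to outcome assessment, the
# second the rest of year 1, then annual cycles.
cycle_grid <- function(max_cycles) {
  dur <- c(0.25, 0.75, rep(1, max_cycles - 2))
  start <- c(0, cumsum(dur))[seq_len(max_cycles)]
  list(dur = dur, start = start, mid = start + dur / 2)
}

# Discounted expected person-time accrual factors: for every entry age
# (0..110) and health state, the expected discounted years alive weighted
# by cycle midpoints, with half-cycle correction in the cycle of death.
# QALYs and costs are this annuity times the state's utility / annual cost,
# so probabilistic draws of utilities and costs reuse the same factors.
# No additional mortality is applied in the first (90-day) cycle: deaths in
# the acute phase are already captured by entry in mRS 6.
annuity_factors <- function(mortality, discount) {
  g <- cycle_grid(mortality$max_cycles)
  ages <- 0:110
  states <- ALL_STATES
  A <- matrix(0, length(ages), length(states),
              dimnames = list(ages, states))
  by_year <- array(0, c(length(ages), length(states), mortality$max_cycles - 1))
  df <- (1 + discount)^(-g$mid)
  for (s in seq_along(states)) {
    hr <- state_hr(states[s], mortality)
    if (is.infinite(hr)) next  # mrs6: dead at entry, accrues nothing
    S <- rep(1, length(ages))
    for (k in seq_len(mortality$max_cycles)) {
      if (k == 1) {
        credit <- g$dur[1] * df[1] * S
      } else {
        age_k <- ages + floor(g$start[k] + 1e-9)
        p <- 1 - exp(-hr * base_hazard(age_k, mortality) * g$dur[k])
        credit <- g$dur[k] * df[k] * S * (1 - p / 2)
        S <- S * (1 - p)
      }
      A[, s] <- A[, s] + credit
      yr <- if (k <= 2) 1L else k - 1L
      by_year[, s, yr] <- by_year[, s, yr] + credit
    }
  }
  list(total = A, by_year = by_year)
}

# Lookup tables of discounted lifetime QALYs and costs per (entry age,
# 90-day state). Recomputed cheaply when utilities/costs change; the
# annuity factors can be reused across parameter draws that leave mortality
# and discounting untouched.
lifetime_lookup <- function(econ, mortality,
                            ann_e = NULL, ann_c = NULL) {
  if (is.null(ann_e)) ann_e <- annuity_factors(mortality, econ$discount_effects)
  if (is.null(ann_c)) ann_c <- annuity_factors(mortality, econ$discount_costs)
  u <- c(econ$utility_by_mrs, 0, econ$utility_nonstroke)
  cst <- c(econ$annual_cost_by_mrs, 0, econ$annual_cost_nonstroke)
  list(qaly = sweep(ann_e$total, 2, u, `*`),
       cost = sweep(ann_c$total, 2, cst, `*`),
       qaly_by_year = sweep(ann_e$by_year, 2, u, `*`),
       cost_by_year = sweep(ann_c$by_year, 2, cst, `*`))
}

#' Discounted lifetime QALYs and costs from the 90-day state
#'
#' The patient enters at age `age` in state `mrs90` (0--6 or
#' `"nonstroke"`) and remains in that state until death. Cycle 1 lasts 3
#' months (the acute phase ending at the 90-day assessment; no additional
#' mortality is applied there because acute deaths enter as mRS 6), cycle 2
#' lasts 9 months, and subsequent cycles last 1 year, up to `max_cycles`
#' cycles after which all patients are assumed dead. Utilities and costs
#' accrue pro rata, discounting uses cycle midpoints, and half-cycle
#' correction credits half the cycle in the cycle of death. `expected` mode
#' computes the closed-form survival-weighted sum; `microsim` mode draws
#' the death cycle.
#'
#' @param mrs90 mRS 0--6 or `"nonstroke"`
#' @param age age at stroke (years)
#' @param econ [economic_params()]
#' @param mortality [mortality_params()]
#' @param mode `"expected"` or `"microsim"`
#' @param seed RNG seed for microsim mode
#' @return list with `qaly_discounted` and `cost_discounted`
#' @export
lifetime_value <- function(mrs90, age, econ = economic_params(),
                           mortality = mortality_params(),
                           mode = c("expected", "microsim"), seed = 1L) {
  mode <- match.arg(mode)
  state <- if (is.numeric(mrs90)) MRS_STATES[mrs90 + 1] else mrs90
  if (!state %in% ALL_STATES) stop("mrs90 must be 0..6 or 'nonstroke'")
  age <- min(max(floor(age), 0), 110)
  u <- c(econ$utility_by_mrs, 0, econ$utility_nonstroke)[match(state, ALL_STATES)]
  cst <- c(econ$annual_cost_by_mrs, 0,
           econ$annual_cost_nonstroke)[match(state, ALL_STATES)]

  if (mode == "expected") {
    lk <- lifetime_lookup(econ, mortality)
    return(list(qaly_discounted = lk$qaly[age + 1, state],
                cost_discounted = lk$cost[age + 1, state]))
  }

  set.seed(seed)
  hr <- state_hr(state, mortality)
  if (is.infinite(hr)) {
    return(list(qaly_discounted = 0, cost_discounted = 0))
  }
  g <- cycle_grid(mortality$max_cycles)
  df_e <- (1 + econ$discount_effects)^(-g$mid)
  df_c <- (1 + econ$discount_costs)^(-g$mid)
  time_alive <- 0
  qaly <- u * g$dur[1] * df_e[1]
  cost <- cst * g$dur[1] * df_c[1]
  for (k in 2:mortality$max_cycles) {
    age_k <- age + floor(g$start[k] + 1e-9)
    p <- 1 - exp(-hr * base_hazard(age_k, mortality) * g$dur[k])
    if (stats::runif(1) < p) {  # dies this cycle: half-cycle credit
      qaly <- qaly + 0.5 * u * g$dur[k] * df_e[k]
      cost <- cost + 0.5 * cst * g$dur[k] * df_c[k]
      break
    }
    qaly <- qaly + u * g$dur[k] * df_e[k]
    cost <- cost + cst * g$dur[k] * df_c[k]
  }
  list(qaly_discounted = qaly, cost_discounted = cost)
}

#' Acute-phase cost per patient
#'
#' Itemised sum: an EMS ride always; the MSU ride when dispatched;
#' treatment costs when given; the interhospital transfer when an
#' EVT-treated patient reached thrombectomy via a primary stroke center;
#' minus the emergency-department deduction when the patient was
#' thrombolysed in the MSU (the ED is bypassed). Acute costs are treated
#' as incurred at time zero and are not discounted.
#'
#' @param msu_dispatched,treated_ivt,treated_evt logical vectors
#' @param routing routing labels from [compute_pathway_times()]
#' @param econ [economic_params()]
#' @return numeric vector of euros
#' @export
acute_cost <- function(msu_dispatched, treated_ivt, treated_evt, routing,
                       econ = economic_params()) {
  ac <- econ$acute_costs
  ac$ems_ride +
    ac$msu_ride * msu_dispatched +
    ac$ivt * treated_ivt +
    ac$evt * treated_evt +
    ac$interhospital_transfer * (routing == "ems_via_psc" & treated_evt) -
    ac$ed_visit_deduction * (msu_dispatched & treated_ivt)
}

#' MSU program cost
#'
#' Investment cost spread over the depreciation period plus operational and
#' personnel costs, scaled by the implementation horizon. Added once to the
#' MSU+EMS strategy total (zero for EMS alone).
#'
#' @param econ [economic_params()]
#' @param horizon_years implementation horizon (> 0)
#' @return euros
#' @export
program_cost <- function(econ = economic_params(), horizon_years = 1) {
  if (horizon_years <= 0) stop("horizon_years must be > 0")
  p <- econ$msu_program
  (p$investment_total / p$depreciation_years +
     p$operational_annual + p$personnel_annual) * horizon_years
}
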