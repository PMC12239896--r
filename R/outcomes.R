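# 90-day outcomes: proportional-odds shift of baseline mRS distributions by
# a treatment effect that decays per minute of onset-to-treatment time.

#' Outcome model parameters
#'
#' Baseline 90-day modified Rankin Scale (mRS 0--6) distributions for
#' untreated ischemic stroke with and without large vessel occlusion and
#' for intracerebral hemorrhage, together with log-odds treatment effects
#' of thrombolysis (IVT) and thrombectomy (EVT) and their per-minute decay.
#' The treatment effect applied to a patient treated at onset-to-treatment
#' time `t` inside the window is `max(0, beta + beta_decay * t)` on the
#' cumulative log-odds scale (a proportional-odds shift toward better
#' outcomes; the floor at zero means late treatment is never modeled as
#' harmful). Baseline distributions and coefficients are stand-in defaults
#' in the spirit of trial control arms and ordinal reanalyses, not
#' authoritative estimates.
#'
#' @param mrs_untreated_nonlvo,mrs_untreated_lvo,mrs_ich 7-probability
#'   vectors over mRS 0--6, each summing to 1
#' @param beta_ivt,beta_evt treatment effects at time zero (log-odds > 0
#'   favors lower mRS)
#' @param beta_ivt_decay,beta_evt_decay change in log-odds per minute of
#'   onset-to-treatment time (<= 0 expected)
#' @param ivt_window,evt_window treatment windows in minutes (4.5 h / 6 h)
#' @param p_ivt_given_eligible probability an ischemic stroke patient
#'   presenting inside the IVT window receives IVT
#' @param p_evt_given_lvo_eligible probability an LVO patient inside the
#'   EVT window receives EVT
#' @param additive_lvo_effects apply IVT and EVT effects additively on the
#'   log-odds scale for LVO patients receiving both (otherwise the larger
#'   single effect is used)
#' @return an `outcome_model` list
#' @export
outcome_model <- function(
    mrs_untreated_nonlvo = c(0.20, 0.20, 0.16, 0.14, 0.12, 0.08, 0.10),
    mrs_untreated_lvo = c(0.05, 0.08, 0.13, 0.16, 0.22, 0.15, 0.21),
    mrs_ich = c(0.05, 0.10, 0.12, 0.15, 0.18, 0.15, 0.25),
    beta_ivt = 1.1, beta_ivt_decay = -0.0035,
    beta_evt = 1.5, beta_evt_decay = -0.003,
    ivt_window = 270, evt_window = 360,
    p_ivt_given_eligible = 0.55, p_evt_given_lvo_eligible = 0.85,
    additive_lvo_effects = TRUE) {
  for (v in list(mrs_untreated_nonlvo, mrs_untreated_lvo, mrs_ich)) {
    if (length(v) != 7 || any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop("mRS vectors must be 7 non-negative probabilities summing to 1")
    }
  }
  if (ivt_window <= 0 || evt_window <= 0) stop("treatment windows must be > 0")
  probs <- c(p_ivt_given_eligible, p_evt_given_lvo_eligible)
  if (any(probs < 0 | probs > 1)) stop("receipt probabilities must be in [0, 1]")
  structure(list(
    mrs_untreated_nonlvo = mrs_untreated_nonlvo,
    mrs_untreated_lvo = mrs_untreated_lvo,
    mrs_ich = mrs_ich,
    beta_ivt = beta_ivt, beta_ivt_decay = beta_ivt_decay,
    beta_evt = beta_evt, beta_evt_decay = beta_evt_decay,
    ivt_window = ivt_window, evt_window = evt_window,
    p_ivt_given_eligible = p_ivt_given_eligible,
    p_evt_given_lvo_eligible = p_evt_given_lvo_eligible,
    additive_lvo_effects = additive_lvo_effects), class = "outcome_model")
}

#' Proportional-odds shift of an ordinal distribution
#'
#' Adds `delta` to the logit of every cumulative probability
#' P(mRS <= k), k = 0..5, and recovers category probabilities by
#' differencing. Positive `delta` moves mass toward lower (better) mRS.
#' Cumulative probabilities of exactly 0 or 1 are clamped to
#' [1e-12, 1 - 1e-12] before the logit so degenerate cells pass through
#' unchanged.
#'
#' @param base 7-probability vector over mRS 0--6
#' @param delta shift on the cumulative log-odds scale
#' @return shifted 7-probability vector
#' @export
shift_distribution <- function(base, delta) {
  if (length(base) != 7 || any(base < 0) || abs(sum(base) - 1) > 1e-9) {
    stop("base must be 7 non-negative probabilities summing to 1")
  }
  if (delta == 0) return(base)
  cum <- pmin(pmax(cumsum(base[1:6]), 1e-12), 1 - 1e-12)
  shifted <- stats::plogis(stats::qlogis(cum) + delta)
  out <- diff(c(0, shifted, 1))
  # guard against tiny negative values from floating point
  pmax(out, 0) / sum(pmax(out, 0))
}

#' Time-decayed treatment effect
#'
#' Log-odds effect of treatment initiated at onset-to-treatment time `ott`:
#' `max(0, beta + beta_decay * ott)` inside the window, 0 at or beyond it.
#' The floor at zero means a decayed effect is never allowed to become
#' harmful.
#'
#' @param beta log-odds effect at time zero
#' @param beta_decay log-odds change per minute (<= 0 expected)
#' @param ott onset-to-treatment time in minutes (>= 0)
#' @param window treatment window in minutes
#' @return log-odds shift (vectorised over `ott`)
#' @export
treatment_delta <- function(beta, beta_decay, ott, window) {
  if (any(ott < 0, na.rm = TRUE)) stop("ott must be >= 0")
  ifelse(!is.na(ott) & ott < window, pmax(0, beta + beta_decay * ott), 0)
}

#' 90-day outcome distribution for one patient
#'
#' Mimics end in the non-stroke health state; TIA ends in mRS 0;
#' intracerebral hemorrhage draws from its own distribution (no MSU
#' treatment effect); ischemic stroke draws from the untreated baseline
#' shifted by the applicable decayed treatment effects.
#'
#' @param diagnosis one of `mimic`, `tia`, `ich`, `ischemic_nonlvo`,
#'   `ischemic_lvo`
#' @param treated_ivt,treated_evt treatment flags (EVT on a non-LVO
#'   diagnosis is a logic error)
#' @param ott_ivt,ott_evt onset-to-treatment times in minutes (required
#'   when the corresponding flag is set)
#' @param model an [outcome_model()]
#' @return for stroke diagnoses, a named 7-probability vector over
#'   mRS 0--6; for mimics, the string `"nonstroke"`
#' @export
outcome_distribution <- function(diagnosis, treated_ivt = FALSE,
                                 treated_evt = FALSE, ott_ivt = NA,
                                 ott_evt = NA, model = outcome_model()) {
  if (treated_evt && diagnosis != "ischemic_lvo") {
    stop("EVT on a non-LVO diagnosis is a logic error")
  }
  if (treated_ivt && !diagnosis %in% c("ischemic_nonlvo", "ischemic_lvo")) {
    stop("IVT applies to ischemic stroke only")
  }
  if (treated_ivt && (is.na(ott_ivt) || ott_ivt >= model$ivt_window)) {
    stop("treated_ivt requires ott_ivt inside the IVT window")
  }
  if (treated_evt && (is.na(ott_evt) || ott_evt >= model$evt_window)) {
    stop("treated_evt requires ott_evt inside the EVT window")
  }
  switch(diagnosis,
    mimic = NONSTROKE_STATE,
    tia = stats::setNames(c(1, rep(0, 6)), MRS_STATES),
    ich = stats::setNames(model$mrs_ich, MRS_STATES),
    ischemic_nonlvo = {
      d <- if (treated_ivt)
        treatment_delta(model$beta_ivt, model$beta_ivt_decay, ott_ivt,
                        model$ivt_window) else 0
      stats::setNames(shift_distribution(model$mrs_untreated_nonlvo, d),
                      MRS_STATES)
    },
    ischemic_lvo = {
      d_ivt <- if (treated_ivt)
        treatment_delta(model$beta_ivt, model$beta_ivt_decay, ott_ivt,
                        model$ivt_window) else 0
      d_evt <- if (treated_evt)
        treatment_delta(model$beta_evt, model$beta_evt_decay, ott_evt,
                        model$evt_window) else 0
      d <- if (model$additive_lvo_effects) d_ivt + d_evt
           else max(d_ivt, d_evt)
      stats::setNames(shift_distribution(model$mrs_untreated_lvo, d),
                      MRS_STATES)
    },
    stop("unknown diagnosis: ", diagnosis))
}

#' Draw a realized mRS state
#'
#' Categorical draw from a 7-probability mRS distribution. With a seed the
#' draw is reproducible; internally the engine passes a retained uniform so
#' the same patient lands on coupled states across strategies (common
#' random numbers with the cumulative-inverse construction).
#'
#' @param dist 7-probability vector over mRS 0--6
#' @param seed RNG seed (ignored when `u` is supplied)
#' @param u optional uniform in (0, 1) to invert
#' @return integer mRS in 0..6
#' @export
draw_mrs <- function(dist, seed = NULL, u = NULL) {
  if (length(dist) != 7 || any(dist < 0) || abs(sum(dist) - 1) > 1e-9) {
    stop("dist must be 7 non-negative probabilities summing to 1")
  }
  if (is.null(u)) {
    if (!is.null(seed)) set.seed(seed)
    u <- stats::runif(1)
  }
  findInterval(u, cumsum(dist[1:6]))
}
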