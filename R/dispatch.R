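# MSU dispatch decisions: operating hours, catchment limit, and single-unit
# (or small-fleet) busy logic over the year of alarms.

#' Scenario specification
#'
#' A dispatch scenario: which site hosts the MSU, its daily operating
#' window, the catchment limit as maximum driving time from the MSU site,
#' and the strategy being simulated.
#'
#' @param msu_site_id dispatch site hosting the MSU
#' @param window_hours daily operating interval in clock hours,
#'   `c(start, end)` with `0 <= start < end <= 24`; `c(0, 24)` is
#'   round-the-clock. The default 7.00--23.00 is the 16-hour base case.
#' @param catchment_min maximum driving time (minutes) from the MSU site for
#'   dispatch; `Inf` covers the entire region
#' @param strategy `"msu_plus_ems"` or `"ems_alone"`
#' @param n_units number of MSUs (first-free assignment when > 1)
#' @return a `scenario_spec` list
#' @export
scenario_spec <- function(msu_site_id = "A", window_hours = c(7, 23),
                          catchment_min = Inf,
                          strategy = c("msu_plus_ems", "ems_alone"),
                          n_units = 1L) {
  strategy <- match.arg(strategy)
  if (length(window_hours) != 2 || window_hours[1] < 0 ||
      window_hours[2] > 24 || window_hours[1] > window_hours[2]) {
    stop("window_hours must be c(start, end) within [0, 24]")
  }
  if (!(catchment_min > 0)) stop("catchment_min must be > 0 (or Inf)")
  if (n_units < 1) stop("n_units must be >= 1")
  structure(list(msu_site_id = msu_site_id, window_hours = window_hours,
                 catchment_min = catchment_min, strategy = strategy,
                 n_units = as.integer(n_units)), class = "scenario_spec")
}

in_operating_window <- function(alarm_time_min, scenario) {
  hour <- (alarm_time_min / 60) %% 24
  hour >= scenario$window_hours[1] & hour < scenario$window_hours[2]
}

#' Is a zone inside the MSU catchment?
#'
#' True iff the driving time from the MSU dispatch site to the zone is less
#' than or equal to the catchment limit (boundary included).
#'
#' @param region a `msu_region`
#' @param scenario a [scenario_spec()]
#' @param zone_id zone id(s)
#' @return logical vector
#' @export
in_catchment <- function(region, scenario, zone_id) {
  if (!scenario$msu_site_id %in% region$sites$site_id) {
    stop("unknown MSU dispatch site: ", scenario$msu_site_id)
  }
  if (!all(zone_id %in% region$zones$zone_id)) {
    stop("unknown zone id(s): ",
         paste(setdiff(zone_id, region$zones$zone_id), collapse = ", "))
  }
  if (is.infinite(scenario$catchment_min)) {
    return(rep(TRUE, length(zone_id)))
  }
  travel_time(region, rep(scenario$msu_site_id, length(zone_id)),
              zone_id) <= scenario$catchment_min
}

# Deterministic per-patient busy duration for the MSU mission, in minutes:
# drive to scene + total on-scene time + (optionally) escort to the
# receiving hospital + return to base. The receiving hospital follows the
# routing rule (nearest TSC for LVO, nearest stroke center otherwise).
msu_busy_durations <- function(cohort, region, scenario, time_params,
                               routing = NULL) {
  if (nrow(cohort) == 0) return(numeric(0))
  if (is.null(routing)) routing <- region_routing(region)
  r <- routing[match(cohort$zone_id, routing$zone_id), ]
  to_scene <- travel_time(region,
                          rep(scenario$msu_site_id, nrow(cohort)),
                          cohort$zone_id)
  lvo <- cohort$diagnosis == "ischemic_lvo"
  dest <- ifelse(lvo & !is.na(r$tsc_id), r$tsc_id, r$near_id)
  to_hospital <- ifelse(lvo & !is.na(r$tsc_id), r$tsc_min, r$near_min)
  if (time_params$msu_escort_to_hospital) {
    back <- vapply(seq_len(nrow(cohort)), function(i) {
      if (has_travel_time(region, scenario$msu_site_id, dest[i])) {
        travel_time(region, scenario$msu_site_id, dest[i])
      } else {
        to_scene[i] + to_hospital[i]  # fallback: retrace via the scene
      }
    }, numeric(1))
    to_scene + time_params$msu_on_scene_total_mean + to_hospital + back
  } else {
    to_scene + time_params$msu_on_scene_total_mean + to_scene
  }
}

#' Simulate MSU availability over the year
#'
#' Chronological sweep over eligible alarms. The MSU is dispatched iff the
#' alarm falls inside the daily operating window, the zone is inside the
#' catchment, and a unit is free; otherwise the reason is recorded
#' (mutually exclusive, checked in that order). Once dispatched, a unit is
#' busy for the mission duration (drive to scene, on-scene assessment,
#' escort to the receiving hospital when configured, return to base). EMS
#' capacity is not modeled: conventional ambulances are always available.
#'
#' The availability fraction is the number of MSU dispatches divided by the
#' number of eligible alarms arising inside the catchment, matching how
#' per-scenario availability is conventionally tabulated. The count of all
#' eligible alarms is also returned.
#'
#' @param cohort a `msu_cohort`
#' @param region a `msu_region`
#' @param scenario a [scenario_spec()]
#' @param time_params [time_params()] (busy-interval composition)
#' @param seed unused by the default deterministic busy model; kept so
#'   stochastic busy models remain reproducible
#' @return list with `log` (data.frame: patient_id, msu_dispatched, reason,
#'   busy_start, busy_end), `availability_fraction`, `n_dispatched`,
#'   `n_eligible`, `n_eligible_in_catchment`
#' @export
simulate_availability <- function(cohort, region, scenario,
                                  time_params = time_params(), seed = 1L) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  elig <- elig[order(elig$alarm_time_min), , drop = FALSE]
  n <- nrow(elig)
  log <- data.frame(patient_id = elig$patient_id,
                    msu_dispatched = rep(FALSE, n),
                    reason = rep(NA_character_, n),
                    busy_start = rep(NA_real_, n),
                    busy_end = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  in_catch <- if (n) in_catchment(region, scenario, elig$zone_id) else logical(0)

  if (scenario$strategy == "ems_alone") {
    log$reason <- rep("strategy_ems_alone", n)
  } else if (n > 0) {
    in_win <- in_operating_window(elig$alarm_time_min, scenario)
    durations <- msu_busy_durations(elig, region, scenario, time_params)
    free_at <- rep(-Inf, scenario$n_units)
    for (i in seq_len(n)) {
      t <- elig$alarm_time_min[i]
      if (!in_win[i]) {
        log$reason[i] <- "outside_hours"
      } else if (!in_catch[i]) {
        log$reason[i] <- "outside_catchment"
      } else {
        unit <- which(free_at <= t)
        if (length(unit) == 0) {
          log$reason[i] <- "busy"
        } else {
          log$msu_dispatched[i] <- TRUE
          log$busy_start[i] <- t
          log$busy_end[i] <- t + durations[i]
          free_at[unit[1]] <- t + durations[i]
        }
      }
    }
  }
  n_in_catch <- sum(in_catch)
  n_disp <- sum(log$msu_dispatched)
  list(log = log,
       availability_fraction = if (n_in_catch > 0) n_disp / n_in_catch
                               else NA_real_,
       n_dispatched = n_disp,
       n_eligible = n,
       n_eligible_in_catchment = n_in_catch)
}
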