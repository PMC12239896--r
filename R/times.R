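# Onset-to-treatment time composition for IVT and EVT under each strategy
# and routing, from alarm, travel, on-scene and in-hospital workflow
# components.

#' Time parameters
#'
#' Prehospital and transfer time components. Dispatch-to-arrival is the
#' activation delay plus the site-to-zone driving time, multiplied by a
#' per-patient log-normal noise factor with mean 1 (`sdlog` controls its
#' spread; 0 makes the component deterministic). On-scene times are
#' per-patient log-normal around their means with the same noise mechanism.
#' In-hospital workflow times (door-to-needle, door-to-groin,
#' door-in-door-out) are hospital-specific and come from the region.
#' Defaults are plausible operational values, not authoritative regional
#' estimates.
#'
#' @param ems_activation_min,msu_activation_min call-to-wheels-rolling delay
#' @param ems_on_scene_mean mean EMS on-scene time (minutes)
#' @param msu_on_scene_to_needle_mean mean MSU time from arrival on scene to
#'   thrombolysis start (imaging, decision, needle)
#' @param msu_on_scene_total_mean mean total MSU on-scene time (needle
#'   happens before departure, so this is >= the time to needle)
#' @param transfer_handover_min fixed handover time added to an
#'   interhospital transfer
#' @param travel_noise_sdlog,scene_noise_sdlog log-sd of the multiplicative
#'   noise on driving and on-scene components
#' @param dtg_prenotification_factor multiplier on the receiving center's
#'   door-to-groin time after a transfer (1 = no pre-notification benefit)
#' @param msu_escort_to_hospital does the MSU accompany the patient to the
#'   receiving hospital before returning to base (affects the busy interval
#'   only)?
#' @return a `time_params` list
#' @export
time_params <- function(ems_activation_min = 2, msu_activation_min = 2,
                        ems_on_scene_mean = 25,
                        msu_on_scene_to_needle_mean = 23,
                        msu_on_scene_total_mean = 33,
                        transfer_handover_min = 10,
                        travel_noise_sdlog = 0.2,
                        scene_noise_sdlog = 0.2,
                        dtg_prenotification_factor = 1,
                        msu_escort_to_hospital = TRUE) {
  vals <- c(ems_activation_min, msu_activation_min, ems_on_scene_mean,
            msu_on_scene_to_needle_mean, msu_on_scene_total_mean,
            transfer_handover_min, travel_noise_sdlog, scene_noise_sdlog,
            dtg_prenotification_factor)
  if (any(vals < 0)) stop("time parameters must be >= 0")
  if (msu_on_scene_total_mean < msu_on_scene_to_needle_mean) {
    stop("msu_on_scene_total_mean must be >= msu_on_scene_to_needle_mean")
  }
  structure(list(ems_activation_min = ems_activation_min,
                 msu_activation_min = msu_activation_min,
                 ems_on_scene_mean = ems_on_scene_mean,
                 msu_on_scene_to_needle_mean = msu_on_scene_to_needle_mean,
                 msu_on_scene_total_mean = msu_on_scene_total_mean,
                 transfer_handover_min = transfer_handover_min,
                 travel_noise_sdlog = travel_noise_sdlog,
                 scene_noise_sdlog = scene_noise_sdlog,
                 dtg_prenotification_factor = dtg_prenotification_factor,
                 msu_escort_to_hospital = msu_escort_to_hospital),
            class = "time_params")
}

# Common random numbers: one uniform per patient per stochastic component,
# drawn once and reused across strategies and parameter draws so that
# strategy comparisons are paired at the patient level.
draw_crn <- function(n, seed) {
  set.seed(seed)
  data.frame(u_ems_travel = stats::runif(n), u_msu_travel = stats::runif(n),
             u_ems_scene = stats::runif(n), u_msu_scene = stats::runif(n),
             u_ivt = stats::runif(n), u_evt = stats::runif(n),
             u_mrs = stats::runif(n), u_life = stats::runif(n))
}

# mean-1 multiplicative log-normal noise from a uniform
lnorm_noise <- function(u, sdlog) {
  if (sdlog == 0) return(rep(1, length(u)))
  stats::qlnorm(u, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Nearest EMS dispatch site per zone (minutes), used for the EMS
# dispatch-to-arrival leg.
nearest_site_minutes <- function(region, zone_id) {
  s <- region$sites$site_id
  mins <- vapply(s, function(sid)
    travel_time(region, rep(sid, length(zone_id)), zone_id), numeric(length(zone_id)))
  if (length(zone_id) == 1) min(mins) else apply(mins, 1, min)
}

#' Compose per-patient pathway times for a whole cohort
#'
#' Vectorised engine behind [pathway_times()]. For every patient the
#' breakdown carries the components of the onset-to-treatment times under
#' the given strategy arm:
#'
#' * MSU arm (dispatched patients): thrombolysis happens on scene, so
#'   `ott_ivt = onset_to_alarm + dispatch_to_arrival +
#'   msu_on_scene_to_needle`. An LVO patient is then escorted directly to
#'   the nearest thrombectomy-capable center:
#'   `ott_evt = onset_to_alarm + dispatch_to_arrival + msu_on_scene_total +
#'   travel(zone -> TSC) + door_to_groin`.
#' * EMS arm (and non-dispatched patients in the MSU strategy): the patient
#'   is taken to the nearest stroke center,
#'   `ott_ivt = onset_to_alarm + dispatch_to_arrival + on_scene +
#'   travel(zone -> nearest) + door_to_needle`. For LVO, if the nearest
#'   center is thrombectomy-capable, `ott_evt` replaces door-to-needle with
#'   door-to-groin; otherwise a drip-and-ship transfer adds
#'   door-in-door-out, the PSC-to-TSC driving time, a handover, and the
#'   receiving center's door-to-groin.
#'
#' @param cohort a `msu_cohort` (only eligible patients are meaningful here)
#' @param msu_dispatched logical vector, one per patient
#' @param region a `msu_region`
#' @param scenario a [scenario_spec()]
#' @param tp [time_params()]
#' @param crn common-random-number frame from the same cohort (internal);
#'   pass the same frame for both arms to pair the comparison
#' @return data.frame of class `time_breakdown`
#' @export
compute_pathway_times <- function(cohort, msu_dispatched, region, scenario,
                                  tp = time_params(), crn) {
  n <- nrow(cohort)
  stopifnot(length(msu_dispatched) == n, nrow(crn) == n)
  routing <- region_routing(region)
  r <- routing[match(cohort$zone_id, routing$zone_id), , drop = FALSE]
  lvo <- cohort$diagnosis == "ischemic_lvo"
  if (any(lvo & is.na(r$tsc_id))) {
    stop("LVO pathway requires at least one thrombectomy-capable center")
  }

  ems_site_min <- nearest_site_minutes(region, cohort$zone_id)
  msu_site_min <- travel_time(region, rep(scenario$msu_site_id, n),
                              cohort$zone_id)
  ems_d2a <- tp$ems_activation_min +
    ems_site_min * lnorm_noise(crn$u_ems_travel, tp$travel_noise_sdlog)
  msu_d2a <- tp$msu_activation_min +
    msu_site_min * lnorm_noise(crn$u_msu_travel, tp$travel_noise_sdlog)
  ems_scene <- tp$ems_on_scene_mean *
    lnorm_noise(crn$u_ems_scene, tp$scene_noise_sdlog)
  msu_scene_noise <- lnorm_noise(crn$u_msu_scene, tp$scene_noise_sdlog)
  msu_needle <- tp$msu_on_scene_to_needle_mean * msu_scene_noise
  msu_scene_total <- tp$msu_on_scene_total_mean * msu_scene_noise

  o2a <- cohort$onset_to_alarm_min
  disp <- msu_dispatched

  # routing label
  routing_lbl <- ifelse(disp,
                        ifelse(lvo, "msu_direct_tsc", "msu_to_psc"),
                        ifelse(lvo,
                               ifelse(r$near_is_tsc, "ems_direct_tsc",
                                      "ems_via_psc"),
                               "ems_to_psc"))

  d2a <- ifelse(disp, msu_d2a, ems_d2a)
  on_scene <- ifelse(disp, msu_scene_total, ems_scene)
  scene_to_hosp <- ifelse(disp & lvo, r$tsc_min, r$near_min)
  dtn <- ifelse(disp, NA_real_, r$near_dtn)
  dido <- ifelse(routing_lbl == "ems_via_psc", r$near_dido, NA_real_)
  transfer <- ifelse(routing_lbl == "ems_via_psc",
                     r$transfer_min + tp$transfer_handover_min, NA_real_)
  dtg_direct <- ifelse(disp, r$tsc_dtg,
                       ifelse(r$near_is_tsc, r$near_dtg, NA_real_))
  dtg_after_transfer <- r$tsc_dtg * tp$dtg_prenotification_factor

  ott_ivt <- ifelse(disp,
                    o2a + msu_d2a + msu_needle,
                    o2a + ems_d2a + ems_scene + r$near_min + r$near_dtn)
  ott_evt <- rep(NA_real_, n)
  i <- disp & lvo
  ott_evt[i] <- (o2a + msu_d2a + msu_scene_total + r$tsc_min + r$tsc_dtg)[i]
  i <- !disp & lvo & r$near_is_tsc
  ott_evt[i] <- (o2a + ems_d2a + ems_scene + r$near_min + r$near_dtg)[i]
  i <- !disp & lvo & !r$near_is_tsc
  ott_evt[i] <- (o2a + ems_d2a + ems_scene + r$near_min + r$near_dido +
                 r$transfer_min + tp$transfer_handover_min +
                 dtg_after_transfer)[i]

  dtg <- ifelse(lvo, ifelse(routing_lbl == "ems_via_psc",
                            dtg_after_transfer, dtg_direct), NA_real_)
  out <- data.frame(
    patient_id = cohort$patient_id,
    routing = routing_lbl,
    onset_to_alarm = o2a,
    dispatch_to_arrival = d2a,
    on_scene = on_scene,
    scene_to_hospital = scene_to_hosp,
    dtn = dtn, dido = dido, transfer = transfer, dtg = dtg,
    ott_ivt = ott_ivt, ott_evt = ott_evt,
    stringsAsFactors = FALSE)
  class(out) <- c("time_breakdown", "data.frame")
  out
}

#' Pathway times for a single patient
#'
#' Convenience wrapper over [compute_pathway_times()] for one patient.
#'
#' @param patient one-row `msu_cohort` data.frame
#' @param msu_dispatched was the MSU dispatched to this patient?
#' @param region a `msu_region`
#' @param scenario a [scenario_spec()]
#' @param tp [time_params()]
#' @param seed RNG seed for the stochastic components
#' @return one-row `time_breakdown`
#' @export
pathway_times <- function(patient, msu_dispatched, region, scenario,
                          tp = time_params(), seed = 1L) {
  if (nrow(patient) != 1) stop("patient must be a single row")
  if (!isTRUE(patient$eligible)) stop("patient is not eligible (onset-to-alarm >= 6 h)")
  crn <- draw_crn(1, seed)
  compute_pathway_times(patient, msu_dispatched, region, scenario, tp, crn)
}

#' Median onset-to-treatment time savings by subgroup
#'
#' Compares matched per-patient breakdowns from the two strategies
#' (simulated with common random numbers) and reports the median of
#' (EMS-arm time minus MSU-arm time) for the subgroups: non-LVO ischemic
#' stroke (thrombolysis times), LVO whose nearest center is
#' thrombectomy-capable (thrombectomy times, direct transport in both
#' arms), and LVO routed through a primary stroke center under EMS
#' (thrombectomy times, transfer avoided by the MSU). Only patients with an
#' MSU dispatch contribute; empty subgroups are reported as `NA`.
#'
#' @param cohort a `msu_cohort`
#' @param bd_msu breakdowns under the MSU+EMS strategy
#' @param bd_ems breakdowns under the EMS-alone strategy
#' @param msu_dispatched logical vector aligned with `cohort`
#' @return data.frame with columns `subgroup`, `n`, `median_saving_min`
#' @export
time_savings_summary <- function(cohort, bd_msu, bd_ems, msu_dispatched) {
  stopifnot(identical(bd_msu$patient_id, bd_ems$patient_id),
            identical(cohort$patient_id, bd_msu$patient_id))
  lvo <- cohort$diagnosis == "ischemic_lvo"
  nonlvo <- cohort$diagnosis == "ischemic_nonlvo"
  via_psc <- bd_ems$routing == "ems_via_psc"
  groups <- list(
    nonlvo_ivt = list(sel = msu_dispatched & nonlvo,
                      d = bd_ems$ott_ivt - bd_msu$ott_ivt),
    lvo_direct_tsc_evt = list(sel = msu_dispatched & lvo & !via_psc,
                              d = bd_ems$ott_evt - bd_msu$ott_evt),
    lvo_via_psc_evt = list(sel = msu_dispatched & lvo & via_psc,
                           d = bd_ems$ott_evt - bd_msu$ott_evt))
  out <- data.frame(
    subgroup = names(groups),
    n = vapply(groups, function(g) sum(g$sel), integer(1)),
    median_saving_min = vapply(groups, function(g) {
      if (sum(g$sel) == 0) NA_real_ else stats::median(g$d[g$sel])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
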