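# In-code fixtures shared across test files. Everything is built
# programmatically; nothing is read from disk.

# Minimal zone table: all population in the 70-74 band unless given.
make_zones <- function(ids, x, y, pop = 1000, band = "pop_70_74") {
  ab <- age_bands()
  z <- data.frame(zone_id = ids, x_km = x, y_km = y,
                  stringsAsFactors = FALSE)
  for (col in ab$column) z[[col]] <- 0L
  z[[band]] <- rep_len(pop, length(ids))
  z
}

make_hospitals <- function(ids, tsc, dtn = 25, dtg = 30, dido = 30,
                           x = 0, y = 0) {
  data.frame(hospital_id = ids, x_km = rep_len(x, length(ids)),
             y_km = rep_len(y, length(ids)), tsc = tsc,
             dtn_min = rep_len(dtn, length(ids)),
             dtg_min = ifelse(tsc, rep_len(dtg, length(ids)), NA_real_),
             dido_min = ifelse(!tsc, rep_len(dido, length(ids)), NA_real_),
             stringsAsFactors = FALSE)
}

make_sites <- function(ids = "A", x = 0, y = 0) {
  data.frame(site_id = ids, x_km = rep_len(x, length(ids)),
             y_km = rep_len(y, length(ids)),
             msu_capable = TRUE, stringsAsFactors = FALSE)
}

# full travel table from a named minutes list "from|to" = minutes
make_travel <- function(...) {
  m <- c(...)
  parts <- strsplit(names(m), "|", fixed = TRUE)
  data.frame(from_id = vapply(parts, `[`, "", 1),
             to_id = vapply(parts, `[`, "", 2),
             minutes = unname(m), stringsAsFactors = FALSE)
}

# One zone, one PSC 20 min away, one TSC 40 min away; the drip-and-ship
# example region used by the hand-traced timeline tests.
toy_region <- function(dido = 30, transfer = 5, dtg = 30, dtn = 25) {
  region(
    zones = make_zones("Z1", 0, 0),
    hospitals = data.frame(
      hospital_id = c("H1", "H2"), x_km = c(1, 2), y_km = 0,
      tsc = c(FALSE, TRUE), dtn_min = dtn,
      dtg_min = c(NA, dtg), dido_min = c(dido, NA),
      stringsAsFactors = FALSE),
    sites = make_sites("A"),
    travel = make_travel("A|Z1" = 10, "Z1|H1" = 20, "Z1|H2" = 40,
                         "H1|H2" = transfer, "A|H1" = 15, "A|H2" = 35))
}

# deterministic time parameters (no sampling noise)
quiet_times <- function(...) {
  time_params(travel_noise_sdlog = 0, scene_noise_sdlog = 0, ...)
}

# hand-written patient rows
make_patients <- function(n, zone_id = "Z1", diagnosis = "ischemic_nonlvo",
                          onset = 30, alarm = 8 * 60, age = 74) {
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             age = rep_len(age, n), zone_id = rep_len(zone_id, n),
             diagnosis = rep_len(diagnosis, n),
             onset_to_alarm_min = rep_len(onset, n),
             alarm_time_min = rep_len(alarm, n),
             eligible = rep_len(onset, n) < 360,
             u_diag = rep_len(0.5, n), stringsAsFactors = FALSE)
}

# cached small synthetic region + cohort for the heavier suites
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      r <- generate_synthetic_region(n_zones = 25, total_population = 8e4,
                                     n_psc = 3, n_tsc = 1, seed = 42)
      co <- generate_cohort(r, seed = 42)
      cache <<- list(region = r, cohort = co)
    }
    cache
  }
})

# configuration with all strategy differences switched off: no treatment
# effect, no MSU-specific acute costs, no program cost
null_effect_config <- function() {
  cfg <- model_config()
  cfg$outcome$beta_ivt <- 0
  cfg$outcome$beta_evt <- 0
  cfg$outcome$beta_ivt_decay <- 0
  cfg$outcome$beta_evt_decay <- 0
  cfg$econ$acute_costs$msu_ride <- 0
  cfg$econ$acute_costs$ed_visit_deduction <- 0
  cfg$econ$acute_costs$interhospital_transfer <- 0
  # treatment costs would otherwise differ when a faster arm converts an
  # untreated patient into a treated one inside the window
  cfg$econ$acute_costs$ivt <- 0
  cfg$econ$acute_costs$evt <- 0
  cfg$econ$msu_program$investment_total <- 0
  cfg$econ$msu_program$operational_annual <- 0
  cfg$econ$msu_program$personnel_annual <- 0
  cfg
}
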