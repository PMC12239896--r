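# Virtual cohort of suspected stroke presentations: one year of stroke
# alarms with diagnosis, age, zone, onset-to-alarm delay and alarm clock
# time.

#' Epidemiology parameters
#'
#' Age-band incidence of suspected stroke (stroke alarms, so mimics are
#' included), diagnosis mix, and the onset-to-alarm delay distribution. The
#' default incidence profile rises steeply with age and is calibrated so
#' that a 1.77-million-inhabitant region with an approximately national age
#' structure produces about 5,500 suspected stroke alarms per year. The
#' onset-to-alarm delay is a mixture of a short-delay spike (witnessed
#' onsets with an immediate call) and a heavy-tailed log-normal; the
#' log-normal location is solved so that the overall probability of an
#' onset-to-alarm time under 6 hours equals `p_alarm_lt_6h`. Diagnosis
#' defaults are registry-style values: the non-ischemic share (mimic + TIA
#' + ICH) is 48%, and 23% of ischemic strokes are large vessel occlusions.
#' All default values are stand-ins, not authoritative regional estimates.
#'
#' @param incidence_by_age suspected-stroke rate per person-year, one value
#'   per 5-year age band (0--4 ... 95+)
#' @param p_mimic,p_tia,p_ich diagnosis probabilities; the remainder is
#'   ischemic stroke
#' @param p_lvo_given_ischemic probability an ischemic stroke is an LVO
#' @param onset_spike_prob weight of the short-delay mixture component
#' @param onset_spike_range uniform range (minutes) of the short-delay
#'   component
#' @param onset_lnorm_sdlog log-sd of the log-normal component
#' @param p_alarm_lt_6h target fraction of alarms with onset-to-alarm < 6 h;
#'   fixes the log-normal location
#' @param diurnal_weights optional 24-vector of relative alarm rates per
#'   clock hour (default uniform)
#' @return an `epidemiology_params` list
#' @export
epidemiology_params <- function(
    incidence_by_age = c(rep(0.000237, 9), 0.00095, 0.00158, 0.00237,
                         0.00356, 0.00554, 0.00791, 0.0119, 0.0174,
                         0.0237, 0.0301, 0.0356),
    p_mimic = 0.28, p_tia = 0.12, p_ich = 0.08,
    p_lvo_given_ischemic = 0.23,
    onset_spike_prob = 0.25, onset_spike_range = c(5, 60),
    onset_lnorm_sdlog = 1.2, p_alarm_lt_6h = 0.66,
    diurnal_weights = rep(1, 24)) {
  probs <- c(p_mimic, p_tia, p_ich, p_lvo_given_ischemic)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (p_mimic + p_tia + p_ich > 1) {
    stop("p_mimic + p_tia + p_ich must be <= 1 (remainder is ischemic)")
  }
  if (length(incidence_by_age) != 20 || any(incidence_by_age < 0)) {
    stop("incidence_by_age must be 20 non-negative rates")
  }
  if (p_alarm_lt_6h <= onset_spike_prob || p_alarm_lt_6h > 1) {
    stop("p_alarm_lt_6h must lie in (onset_spike_prob, 1]")
  }
  if (length(diurnal_weights) != 24 || any(diurnal_weights < 0) ||
      sum(diurnal_weights) == 0) {
    stop("diurnal_weights must be 24 non-negative values, not all zero")
  }
  # P(lognormal < 360) needed once the spike (entirely < 6 h) is accounted
  p_tail <- (p_alarm_lt_6h - onset_spike_prob) / (1 - onset_spike_prob)
  meanlog <- log(ELIGIBILITY_GATE_MIN) -
    stats::qnorm(p_tail) * onset_lnorm_sdlog
  structure(list(
    incidence_by_age = incidence_by_age,
    p_mimic = p_mimic, p_tia = p_tia, p_ich = p_ich,
    p_lvo_given_ischemic = p_lvo_given_ischemic,
    onset_spike_prob = onset_spike_prob,
    onset_spike_range = onset_spike_range,
    onset_lnorm_meanlog = meanlog,
    onset_lnorm_sdlog = onset_lnorm_sdlog,
    p_alarm_lt_6h = p_alarm_lt_6h,
    diurnal_weights = diurnal_weights), class = "epidemiology_params")
}

# Map a uniform draw to a diagnosis given the four probabilities. Keeping
# the uniform on the patient record lets sensitivity analyses redraw the
# diagnosis under perturbed probabilities without regenerating the cohort
# (common random numbers at the diagnosis level).
assign_diagnosis <- function(u, epi) {
  p_isch <- 1 - epi$p_mimic - epi$p_tia - epi$p_ich
  cuts <- cumsum(c(epi$p_mimic, epi$p_tia, epi$p_ich,
                   p_isch * (1 - epi$p_lvo_given_ischemic)))
  DIAGNOSES[1L + findInterval(u, cuts)]
}

sample_onset_to_alarm <- function(n, epi) {
  spike <- stats::runif(n) < epi$onset_spike_prob
  out <- numeric(n)
  out[spike] <- stats::runif(sum(spike), epi$onset_spike_range[1],
                             epi$onset_spike_range[2])
  out[!spike] <- stats::rlnorm(sum(!spike), epi$onset_lnorm_meanlog,
                               epi$onset_lnorm_sdlog)
  out
}

sample_alarm_time <- function(n, epi) {
  hour <- sample(0:23, n, replace = TRUE,
                 prob = epi$diurnal_weights / sum(epi$diurnal_weights))
  day <- sample(0:364, n, replace = TRUE)
  day * 1440 + hour * 60 + stats::runif(n, 0, 60)
}

#' Generate the one-year virtual cohort
#'
#' Draws, for every (zone, age band), a Poisson number of suspected stroke
#' presentations with mean population x incidence rate, assigns a diagnosis
#' from the multinomial mix, an age uniform within the band, an alarm clock
#' time over the year, and an onset-to-alarm delay. A patient is eligible
#' for the dispatch model when the onset-to-alarm time is under 6 hours.
#'
#' @param region a `msu_region`
#' @param epi [epidemiology_params()]
#' @param seed RNG seed (same seed, same cohort)
#' @return data.frame of class `msu_cohort` with columns `patient_id`,
#'   `age`, `zone_id`, `diagnosis`, `onset_to_alarm_min`, `alarm_time_min`,
#'   `eligible` and the retained diagnosis uniform `u_diag`
#' @export
generate_cohort <- function(region, epi = epidemiology_params(), seed = 1L) {
  stopifnot(inherits(region, "msu_region"),
            inherits(epi, "epidemiology_params"))
  set.seed(seed)
  ab <- age_bands()
  pop <- as.matrix(region$zones[, ab$column])
  lambda <- sweep(pop, 2, epi$incidence_by_age, `*`)
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda))

  n <- sum(counts)
  if (n == 0) {
    return(empty_cohort())
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  reps <- counts[counts > 0]
  zone_id <- rep(region$zones$zone_id[idx[, 1]], reps)
  band <- rep(idx[, 2], reps)
  lo <- ab$lower[band]
  hi <- ifelse(is.finite(ab$upper[band]), ab$upper[band] + 1, 100)
  age <- floor(stats::runif(n, lo, hi))

  u_diag <- stats::runif(n)
  onset <- sample_onset_to_alarm(n, epi)
  alarm <- sample_alarm_time(n, epi)

  cohort <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = age, zone_id = zone_id,
    diagnosis = assign_diagnosis(u_diag, epi),
    onset_to_alarm_min = onset,
    alarm_time_min = alarm,
    eligible = onset < ELIGIBILITY_GATE_MIN,
    u_diag = u_diag,
    stringsAsFactors = FALSE)
  cohort <- cohort[order(cohort$alarm_time_min), ]
  rownames(cohort) <- NULL
  class(cohort) <- c("msu_cohort", "data.frame")
  cohort
}

empty_cohort <- function() {
  cohort <- data.frame(patient_id = character(), age = numeric(),
                       zone_id = character(), diagnosis = character(),
                       onset_to_alarm_min = numeric(),
                       alarm_time_min = numeric(), eligible = logical(),
                       u_diag = numeric(), stringsAsFactors = FALSE)
  class(cohort) <- c("msu_cohort", "data.frame")
  cohort
}

#' Summarise a cohort
#'
#' Counts by diagnosis and eligibility, plus median age with interquartile
#' range. Quantiles use the standard order-statistic definition
#' (`stats::quantile` type 7).
#'
#' @param cohort a `msu_cohort`
#' @return list with `n`, `n_eligible`, `eligible_fraction`,
#'   `counts_by_diagnosis`, `median_age`, `age_iqr`
#' @export
summarize_cohort <- function(cohort) {
  counts <- vapply(DIAGNOSES, function(d) sum(cohort$diagnosis == d),
                   integer(1))
  if (nrow(cohort) == 0) {
    return(list(n = 0L, n_eligible = 0L, eligible_fraction = NA_real_,
                counts_by_diagnosis = counts, median_age = NA_real_,
                age_iqr = c(NA_real_, NA_real_)))
  }
  list(n = nrow(cohort),
       n_eligible = sum(cohort$eligible),
       eligible_fraction = mean(cohort$eligible),
       counts_by_diagnosis = counts,
       median_age = stats::median(cohort$age),
       age_iqr = unname(stats::quantile(cohort$age, c(0.25, 0.75))))
}

#' Expected cohort size
#'
#' Analytic Poisson expectation: the sum over zones and age bands of
#' population times incidence rate.
#'
#' @param region a `msu_region`
#' @param epi [epidemiology_params()]
#' @return expected number of suspected stroke presentations per year
#' @export
expected_cohort_size <- function(region, epi = epidemiology_params()) {
  ab <- age_bands()
  pop <- as.matrix(region$zones[, ab$column])
  sum(sweep(pop, 2, epi$incidence_by_age, `*`))
}

#' Write a cohort to CSV
#' @param cohort a `msu_cohort`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#' @param path file written by [write_cohort()]
#' @return a `msu_cohort`
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort$eligible <- as.logical(cohort$eligible)
  class(cohort) <- c("msu_cohort", "data.frame")
  cohort
}
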