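# YAML serialisation of the model configuration. Reading goes back through
# the typed constructors so every validation applies to file input too.

block_args <- list(
  epi = c("incidence_by_age", "p_mimic", "p_tia", "p_ich",
          "p_lvo_given_ischemic", "onset_spike_prob", "onset_spike_range",
          "onset_lnorm_sdlog", "p_alarm_lt_6h", "diurnal_weights"),
  times = c("ems_activation_min", "msu_activation_min", "ems_on_scene_mean",
            "msu_on_scene_to_needle_mean", "msu_on_scene_total_mean",
            "transfer_handover_min", "travel_noise_sdlog",
            "scene_noise_sdlog", "dtg_prenotification_factor",
            "msu_escort_to_hospital"),
  outcome = c("mrs_untreated_nonlvo", "mrs_untreated_lvo", "mrs_ich",
              "beta_ivt", "beta_ivt_decay", "beta_evt", "beta_evt_decay",
              "ivt_window", "evt_window", "p_ivt_given_eligible",
              "p_evt_given_lvo_eligible", "additive_lvo_effects"),
  econ = c("utility_by_mrs", "utility_nonstroke", "annual_cost_by_mrs",
           "annual_cost_nonstroke", "acute_costs", "msu_program",
           "discount_effects", "discount_costs", "wtp"),
  mortality = c("annual_mortality_by_age", "hr_by_mrs", "hr_nonstroke",
                "max_cycles"))

block_ctor <- function(b) {
  switch(b, epi = epidemiology_params, times = time_params,
         outcome = outcome_model, econ = economic_params,
         mortality = mortality_params)
}

#' Write a model configuration to YAML
#'
#' @param config a [model_config()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  out <- lapply(names(block_args), function(b) {
    vals <- config[[b]][block_args[[b]]]
    lapply(vals, function(v) if (is.list(v)) v else unclass(v))
  })
  names(out) <- names(block_args)
  out$horizon_years <- config$horizon_years
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' Every block is rebuilt through its constructor, so invalid values in the
#' file raise the same errors as invalid arguments in code.
#'
#' @param path a file written by [write_config()] (unknown keys are an
#'   error; missing keys fall back to defaults)
#' @return a [model_config()]
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  blocks <- lapply(names(block_args), function(b) {
    args <- raw[[b]]
    if (is.null(args)) args <- list()
    unknown <- setdiff(names(args), block_args[[b]])
    if (length(unknown)) {
      stop("unknown key(s) in '", b, "' block: ",
           paste(unknown, collapse = ", "))
    }
    do.call(block_ctor(b), args)
  })
  names(blocks) <- names(block_args)
  model_config(epi = blocks$epi, times = blocks$times,
               outcome = blocks$outcome, econ = blocks$econ,
               mortality = blocks$mortality,
               horizon_years = if (is.null(raw$horizon_years)) 1
                               else raw$horizon_years)
}
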