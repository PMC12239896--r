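# Shared constants (this file collates first).

MINUTES_PER_YEAR <- 525600
ELIGIBILITY_GATE_MIN <- 360  # onset-to-alarm < 6 h enters the model

DIAGNOSES <- c("mimic", "tia", "ich", "ischemic_nonlvo", "ischemic_lvo")

MRS_STATES <- paste0("mrs", 0:6)
NONSTROKE_STATE <- "nonstroke"
ALL_STATES <- c(MRS_STATES, NONSTROKE_STATE)
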