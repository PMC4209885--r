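# Shared fixtures: sessions are generated in code, never stored.

# deterministic subject: equal MVC on all DOFs, no tracking noise or lag
clean_subject <- function(mvc = 20) {
  subject_params(mvc = mvc, tracking_noise_sd = 0, tracking_lag = 0)
}

# short protocol for unit tests (1 s segments); study-condition properties
# use make_protocol() defaults instead
tiny_protocol <- function(force_level = 0.8, n_repetitions = 2L) {
  make_protocol(force_level, n_repetitions = n_repetitions,
                segment_durations = c(rest = 1, ramp_up = 0.5, plateau = 1,
                                      ramp_down = 0.5, rest_post = 1))
}

# noise-free drift-free session over all streams
quiet_session <- function(protocol = tiny_protocol(), subject = clean_subject(),
                          seed = 1L, streams = c("semg", "fsr", "us_features")) {
  cfgs <- lapply(stats::setNames(streams, streams), function(nm) {
    cfg <- default_sensor_config(if (nm == "fsr2") "fsr" else nm, drift = FALSE)
    cfg$noise_sd <- 0
    cfg
  })
  simulate_session(protocol, subject, streams = cfgs, seed = seed)
}

# default-condition session (defaults of the generators; the study conditions)
study_session <- function(seed, phase = "high", subject_id = 1L,
                          streams = c("semg", "fsr"), drift = TRUE) {
  protocol <- make_protocol(if (phase == "high") 0.8 else 0.15)
  subject <- sample_subject(derive_seed(seed, "subject", subject_id))
  cfgs <- lapply(stats::setNames(streams, streams), function(nm) {
    default_sensor_config(if (nm == "fsr2") "fsr" else nm, drift = drift)
  })
  simulate_session(protocol, subject, streams = cfgs, seed = seed,
                   phase = phase, subject_id = subject_id)
}

fast_rff_config <- function(sigma = NULL) {
  list(feature_map = "rff", lambda = 1, D = 300L, sigma = sigma,
       sigma_grid_size = 5L)
}
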