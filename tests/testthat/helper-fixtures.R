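# Shared fixtures: a small sensor model and cheap simulated subjects.
# Everything is built in code at test time; nothing is read from disk.

local_cache <- new.env(parent = emptyenv())

# default-size model, built once per test run
cached_model <- function() {
  if (is.null(local_cache$model)) {
    local_cache$model <- build_sensor_model(seed = 42)
  }
  local_cache$model
}

# small cheap subject: 8-trial session at default amplitudes
small_recording <- function(seed = 1, n_trials = 8, config = NULL) {
  if (is.null(config)) config <- sim_config(n_trials = n_trials,
                                            n_blocks = 2, seed = seed)
  plan <- layout_session(generate_session_plan(n_trials, 2, seed = seed))
  simulate_subject(config, plan, cached_model(), subject_seed = seed + 1L)
}

# constant-f0 pitch track of given duration
const_track <- function(f0, dur_s, fs = 1000) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  pitch_track(t, rep(f0, length(t)))
}
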