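# Shared fixtures, built once per test run. The default session is the full
# study protocol (6 movements x 10 reps at 2 kHz) and is reused by several
# test files; smaller configurations are built inline where speed matters.

.fixture_env <- new.env(parent = emptyenv())

default_session <- function() {
  if (!exists("rec", .fixture_env)) {
    .fixture_env$rec <- generate_session(sim_config(rng_seed = 42L),
                                         subject_id = "S01")
  }
  .fixture_env$rec
}

default_prep <- function() {
  if (!exists("prep", .fixture_env)) {
    .fixture_env$prep <- preprocess_recording(default_session())
  }
  .fixture_env$prep
}

default_events <- function() {
  if (!exists("events", .fixture_env)) {
    .fixture_env$events <- detect_triggers(default_prep()$trigger_native,
                                           default_prep()$native_rate_hz)
  }
  .fixture_env$events
}

default_windows <- function() {
  if (!exists("windows", .fixture_env)) {
    .fixture_env$windows <- extract_windows(default_prep(), default_events())
  }
  .fixture_env$windows
}

# a small, fast configuration (2 movements x 2 reps, ~33 s session)
small_config <- function(...) {
  sim_config(n_movements = 2, reps_per_movement = 2,
             trigger_levels_mV = c(15, 20), ...)
}

# amplitude of a sinusoid at frequency f in x, by complex demodulation over
# an integer number of cycles (edges discarded)
sine_amplitude <- function(x, f, rate, discard_s = 0.25) {
  i0 <- round(discard_s * rate) + 1
  n_cyc <- floor((length(x) - 2 * (i0 - 1)) * f / rate)
  n_keep <- round(n_cyc * rate / f)
  idx <- i0:(i0 + n_keep - 1)
  t <- (idx - 1) / rate
  Mod(2 * mean(x[idx] * exp(-2i * pi * f * t)))
}

run_sim_concordance <- function(noise_sd, seed, exclude = NULL, ...) {
  cfg <- sim_config(prototype_noise_sd = noise_sd, rng_seed = seed, ...)
  rec <- generate_session(cfg)
  prep <- preprocess_recording(rec)
  ev <- detect_triggers(prep$trigger_native, prep$native_rate_hz,
                        levels_mV = cfg$trigger_levels_mV)
  ft <- suppressWarnings(featurize_windows(extract_windows(prep, ev)))
  concordance_matrix(ft, exclude_features = exclude)
}
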