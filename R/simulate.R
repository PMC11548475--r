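#' Simulation configuration for a dual-device EMG session
#'
#' Builds and validates the parameter set driving [generate_session()]. The
#' defaults reproduce the validation protocol the package targets: six
#' movement types, ten repetitions each, 2 s contractions separated by 5 s of
#' rest, acquired at 2 kHz, with trial identity encoded on an analog trigger
#' channel as 5 ms pulses stepping from 15 mV to 40 mV in 5 mV increments.
#'
#' The simulated muscle source is band-limited Gaussian noise (20--300 Hz)
#' amplitude-modulated by a trapezoidal contraction envelope. The reference
#' device sees the source plus low additive noise; the prototype device sees
#' the source passed through a model of its analog front end (first-order
#' high-pass at 20.7 Hz, first-order low-pass at 330 Hz, fourth-order 60 Hz
#' notch, gain) plus higher additive noise.
#'
#' @param sampling_rate_hz acquisition rate in Hz.
#' @param n_movements number of distinct movement types.
#' @param reps_per_movement repetitions of each movement.
#' @param contraction_s contraction (trial) duration, seconds.
#' @param rest_s rest duration between trials, seconds. The session starts
#'   with one rest block and every trial is followed by one, so total
#'   duration is `rest_s + n_trials * (contraction_s + rest_s)`.
#' @param trigger_levels_mV strictly increasing pulse amplitudes (mV), one
#'   per movement; level `k` labels movement `k`.
#' @param trigger_pulse_ms trigger pulse width, milliseconds.
#' @param source_band_hz length-2 numeric, muscle-source band edges in Hz.
#' @param envelope_rise_ms,envelope_fall_ms envelope ramp times, ms.
#' @param reaction_delay_ms mean latency between trigger and contraction
#'   onset, ms.
#' @param reaction_jitter_ms standard deviation of that latency, ms.
#' @param rest_amplitude baseline (resting) envelope amplitude relative to
#'   the contraction amplitude of 1.
#' @param prototype_gain scalar gain of the prototype channel model.
#' @param prototype_hp_hz,prototype_lp_hz,notch_hz corner/notch frequencies
#'   of the prototype analog-chain model, Hz.
#' @param prototype_chain if `FALSE` the analog-chain filters are bypassed
#'   (gain and noise still apply); used for identity-channel checks.
#' @param reference_noise_sd,prototype_noise_sd additive Gaussian noise
#'   standard deviations, in normalized source units.
#' @param mains_amplitude amplitude of a 60 Hz mains component added to the
#'   prototype input before its analog chain (0 disables).
#' @param rng_seed integer seed; [generate_session()] is deterministic in it.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(sampling_rate_hz = 2000,
                       n_movements = 6,
                       reps_per_movement = 10,
                       contraction_s = 2,
                       rest_s = 5,
                       trigger_levels_mV = seq(15, 40, by = 5),
                       trigger_pulse_ms = 5,
                       source_band_hz = c(20, 300),
                       envelope_rise_ms = 200,
                       envelope_fall_ms = 200,
                       reaction_delay_ms = 150,
                       reaction_jitter_ms = 50,
                       rest_amplitude = 0.05,
                       prototype_gain = 1,
                       prototype_hp_hz = 20.7,
                       prototype_lp_hz = 330,
                       notch_hz = 60,
                       prototype_chain = TRUE,
                       reference_noise_sd = 0.02,
                       prototype_noise_sd = 0.08,
                       mains_amplitude = 0,
                       rng_seed = 1L) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz, n_movements = as.integer(n_movements),
    reps_per_movement = as.integer(reps_per_movement),
    contraction_s = contraction_s, rest_s = rest_s,
    trigger_levels_mV = trigger_levels_mV, trigger_pulse_ms = trigger_pulse_ms,
    source_band_hz = source_band_hz,
    envelope_rise_ms = envelope_rise_ms, envelope_fall_ms = envelope_fall_ms,
    reaction_delay_ms = reaction_delay_ms,
    reaction_jitter_ms = reaction_jitter_ms,
    rest_amplitude = rest_amplitude,
    prototype_gain = prototype_gain, prototype_hp_hz = prototype_hp_hz,
    prototype_lp_hz = prototype_lp_hz, notch_hz = notch_hz,
    prototype_chain = isTRUE(prototype_chain),
    reference_noise_sd = reference_noise_sd,
    prototype_noise_sd = prototype_noise_sd,
    mains_amplitude = mains_amplitude, rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  stopifnot_cfg(cfg$sampling_rate_hz > 0, "sampling_rate_hz must be positive")
  stopifnot_cfg(cfg$n_movements >= 1, "n_movements must be >= 1")
  stopifnot_cfg(cfg$reps_per_movement >= 1, "reps_per_movement must be >= 1")
  stopifnot_cfg(cfg$contraction_s > 0 && cfg$rest_s > 0,
                "contraction_s and rest_s must be positive")
  stopifnot_cfg(length(cfg$trigger_levels_mV) == cfg$n_movements,
                "need one trigger level per movement")
  stopifnot_cfg(all(diff(cfg$trigger_levels_mV) > 0),
                "trigger levels must be strictly increasing")
  stopifnot_cfg(cfg$trigger_pulse_ms > 0, "trigger_pulse_ms must be positive")
  stopifnot_cfg(length(cfg$source_band_hz) == 2 &&
                  cfg$source_band_hz[1] > 0 &&
                  cfg$source_band_hz[1] < cfg$source_band_hz[2],
                "source_band_hz must be an increasing positive pair")
  stopifnot_cfg(cfg$source_band_hz[2] < cfg$sampling_rate_hz / 2,
                "source band must lie below Nyquist")
  if (cfg$prototype_chain) {
    stopifnot_cfg(max(cfg$prototype_hp_hz, cfg$prototype_lp_hz, cfg$notch_hz) <
                    cfg$sampling_rate_hz / 2,
                  "prototype filter corners must lie below Nyquist")
  }
  stopifnot_cfg(cfg$reference_noise_sd >= 0 && cfg$prototype_noise_sd >= 0,
                "noise standard deviations must be nonnegative")
  stopifnot_cfg(cfg$reaction_delay_ms >= 0, "reaction_delay_ms must be nonnegative")
  stopifnot_cfg(cfg$rest_amplitude >= 0 && cfg$rest_amplitude <= 0.05,
                "rest_amplitude must lie in [0, 0.05]")
  invisible(cfg)
}

#' Total session duration implied by a configuration
#' @param config a [sim_config()].
#' @return duration in seconds.
#' @export
session_duration_s <- function(config) {
  n_trials <- config$n_movements * config$reps_per_movement
  config$rest_s + n_trials * (config$contraction_s + config$rest_s)
}

#' Build a randomized, balanced trial schedule
#'
#' Produces the presentation order of the session: every movement id appears
#' exactly `reps_per_movement` times, in a seeded random permutation, with
#' consecutive onsets separated by `contraction_s + rest_s`. The first onset
#' falls after an initial rest block of `rest_s`.
#'
#' Uses the R session RNG; seed upstream (as [generate_session()] does) for
#' reproducibility.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `onset_s`, `movement_id`.
#' @export
build_schedule <- function(config) {
  validate_sim_config(config)
  ids <- rep(seq_len(config$n_movements), times = config$reps_per_movement)
  ids <- sample(ids)
  step <- config$contraction_s + config$rest_s
  onsets <- config$rest_s + (seq_along(ids) - 1) * step
  data.frame(onset_s = onsets, movement_id = ids)
}

#' Generate the shared muscle-source signal
#'
#' White Gaussian noise band-limited to `source_band_hz` (fourth-order
#' zero-phase Butterworth), amplitude-modulated by a trapezoidal envelope:
#' near-zero at rest, ramping up over `envelope_rise_ms` starting one
#' reaction delay after each trigger onset, holding for `contraction_s`,
#' then ramping down over `envelope_fall_ms`. The resting baseline amplitude
#' is `rest_amplitude` (at most 5% of the contraction amplitude).
#'
#' @param schedule data.frame from [build_schedule()] (may have zero rows).
#' @param config a [sim_config()].
#' @param duration_s optional duration override, seconds.
#' @return numeric vector of length `round(duration_s * sampling_rate_hz)`.
#' @export
generate_source <- function(schedule, config, duration_s = NULL) {
  validate_sim_config(config)
  fs <- config$sampling_rate_hz
  if (is.null(duration_s)) duration_s <- session_duration_s(config)
  n <- round(duration_s * fs)
  carrier <- stats::rnorm(n)
  bp <- signal::butter(2, config$source_band_hz / (fs / 2), type = "pass")
  carrier <- signal::filtfilt(bp, carrier)
  # unit RMS carrier so the envelope sets amplitude directly
  carrier <- carrier / stats::sd(carrier)

  env <- rep(config$rest_amplitude, n)
  if (nrow(schedule) > 0) {
    delays <- pmax(0, stats::rnorm(nrow(schedule),
                                   mean = config$reaction_delay_ms,
                                   sd = config$reaction_jitter_ms)) / 1000
    rise <- config$envelope_rise_ms / 1000
    fall <- config$envelope_fall_ms / 1000
    t <- (seq_len(n) - 1) / fs
    for (k in seq_len(nrow(schedule))) {
      t0 <- schedule$onset_s[k] + delays[k]
      t1 <- t0 + rise                  # plateau start
      t2 <- t0 + config$contraction_s  # plateau end
      t3 <- t2 + fall
      idx <- which(t >= t0 & t < t3)
      if (!length(idx)) next
      seg <- t[idx]
      val <- ifelse(seg < t1, (seg - t0) / rise,
                    ifelse(seg <= t2, 1, (t3 - seg) / fall))
      env[idx] <- pmax(env[idx], config$rest_amplitude + (1 - config$rest_amplitude) * val)
    }
  }
  carrier * env
}

#' Pass a signal through the prototype front-end model
#'
#' Digital stand-in for the prototype's analog conditioning chain: a
#' first-order Butterworth high-pass at `prototype_hp_hz`, a first-order
#' low-pass at `prototype_lp_hz`, and a fourth-order band-stop notch at
#' `notch_hz` (width `notch_hz/6`), applied causally (single pass, as a
#' physical analog chain is), then scaled by `prototype_gain`, plus additive
#' Gaussian noise of sd `prototype_noise_sd`. Set `prototype_chain = FALSE`
#' in the config to bypass the filters.
#'
#' @param source numeric vector at `sampling_rate_hz`.
#' @param config a [sim_config()].
#' @return numeric vector, same length as `source`.
#' @export
apply_prototype_channel <- function(source, config) {
  validate_sim_config(config)
  fs <- config$sampling_rate_hz
  y <- source
  if (config$prototype_chain) {
    hp <- signal::butter(1, config$prototype_hp_hz / (fs / 2), type = "high")
    lp <- signal::butter(1, config$prototype_lp_hz / (fs / 2), type = "low")
    half_bw <- config$notch_hz / 12
    notch <- signal::butter(2, c(config$notch_hz - half_bw,
                                 config$notch_hz + half_bw) / (fs / 2),
                            type = "stop")
    y <- signal::filter(hp, y)
    y <- signal::filter(lp, y)
    y <- signal::filter(notch, y)
  }
  y <- config$prototype_gain * y
  if (config$prototype_noise_sd > 0) {
    y <- y + stats::rnorm(length(y), sd = config$prototype_noise_sd)
  }
  as.numeric(y)
}

#' Build the analog trigger channel
#'
#' Zero everywhere except a rectangular pulse of width `trigger_pulse_ms` at
#' each scheduled onset, with amplitude `trigger_levels_mV[movement_id]`
#' expressed in volts (15 mV encodes movement 1, stepping 5 mV per movement
#' up to 40 mV for movement 6 under the defaults).
#'
#' @inheritParams generate_source
#' @return numeric vector (volts).
#' @export
make_trigger_channel <- function(schedule, config, duration_s = NULL) {
  validate_sim_config(config)
  fs <- config$sampling_rate_hz
  if (is.null(duration_s)) duration_s <- session_duration_s(config)
  n <- round(duration_s * fs)
  trig <- numeric(n)
  if (nrow(schedule) == 0) return(trig)
  width <- max(1L, round(config$trigger_pulse_ms / 1000 * fs))
  starts <- round(schedule$onset_s * fs) + 1L
  ends <- starts + width - 1L
  if (any(starts[-1] <= ends[-length(ends)])) {
    stop("overlapping trigger pulses in schedule", call. = FALSE)
  }
  amps <- config$trigger_levels_mV[schedule$movement_id] / 1000
  for (k in seq_along(starts)) {
    i0 <- starts[k]
    i1 <- min(ends[k], n)
    if (i0 <= n) trig[i0:i1] <- amps[k]
  }
  trig
}

#' Simulate a complete synchronized dual-device session
#'
#' Composes [build_schedule()], [generate_source()],
#' [apply_prototype_channel()] and [make_trigger_channel()] into one
#' recording: the reference channel is the source plus low additive noise;
#' the prototype channel is the source through the front-end model. All
#' randomness is drawn from a single generator seeded with `rng_seed`, so
#' identical configurations produce bit-identical recordings.
#'
#' @param config a [sim_config()].
#' @param subject_id identifier stored in the recording metadata.
#' @return an object of class `dual_recording`: a list with `time_s`,
#'   `reference_emg`, `prototype_emg`, `trigger`, `sampling_rate_hz`,
#'   `schedule` and `metadata`.
#' @export
generate_session <- function(config = sim_config(), subject_id = "S01") {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$rng_seed)
  schedule <- build_schedule(config)
  duration <- session_duration_s(config)
  source_sig <- generate_source(schedule, config, duration)
  reference <- source_sig
  if (config$reference_noise_sd > 0) {
    reference <- reference + stats::rnorm(length(reference), sd = config$reference_noise_sd)
  }
  proto_in <- source_sig
  if (config$mains_amplitude > 0) {
    t <- (seq_along(proto_in) - 1) / config$sampling_rate_hz
    proto_in <- proto_in + config$mains_amplitude * sin(2 * pi * 60 * t)
  }
  prototype <- apply_prototype_channel(proto_in, config)
  trigger <- make_trigger_channel(schedule, config, duration)
  n <- length(source_sig)
  rec <- list(
    time_s = (seq_len(n) - 1) / config$sampling_rate_hz,
    reference_emg = reference,
    prototype_emg = prototype,
    trigger = trigger,
    sampling_rate_hz = config$sampling_rate_hz,
    schedule = schedule,
    metadata = list(subject_id = subject_id, rng_seed = config$rng_seed,
                    config = unclass(config))
  )
  class(rec) <- "dual_recording"
  rec
}

#' @export
print.dual_recording <- function(x, ...) {
  cat(sprintf("dual_recording: %d samples @ %g Hz (%.1f s), %d scheduled trials, subject %s\n",
              length(x$reference_emg), x$sampling_rate_hz,
              length(x$reference_emg) / x$sampling_rate_hz,
              nrow(x$schedule), x$metadata$subject_id %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
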