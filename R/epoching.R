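#' Detect trigger pulses and decode movement identity
#'
#' Scans the analog trigger channel (at its native, pre-decimation rate,
#' where a 5 ms pulse spans ~10 samples at 2 kHz) for rectangular pulses.
#' A pulse onset is the first sample exceeding half the smallest configured
#' level; its amplitude is the median of the samples within the pulse width;
#' a 1 s refractory period suppresses duplicate detections. Amplitudes are
#' decoded to movement ids with [decode_movement()]; pulses matching no
#' level within tolerance are excluded with a warning.
#'
#' @param trigger numeric trigger series (volts).
#' @param rate sampling rate of `trigger`, Hz.
#' @param levels_mV configured pulse amplitudes in mV, ascending.
#' @param tolerance_mV closed matching tolerance in mV (default 2, half the
#'   5 mV level spacing minus margin).
#' @param pulse_ms nominal pulse width used to measure amplitude.
#' @param refractory_s minimum separation between events, seconds.
#' @return data.frame of class `trigger_events` with columns `onset_index`
#'   (1-based, native grid), `onset_s`, `amplitude_V`, `movement_id`.
#' @export
detect_triggers <- function(trigger, rate, levels_mV = seq(15, 40, by = 5),
                            tolerance_mV = 2, pulse_ms = 5, refractory_s = 1) {
  threshold <- min(levels_mV) / 1000 / 2
  width <- max(1L, round(pulse_ms / 1000 * rate))
  refractory <- round(refractory_s * rate)
  above <- which(trigger > threshold)
  onsets <- integer(0)
  amps <- numeric(0)
  last <- -Inf
  for (i in above) {
    if (i - last < refractory) next
    last <- i
    seg <- trigger[i:min(i + width - 1L, length(trigger))]
    onsets <- c(onsets, i)
    amps <- c(amps, stats::median(seg))
  }
  ids <- vapply(amps, decode_movement, integer(1),
                levels_mV = levels_mV, tolerance_mV = tolerance_mV)
  unknown <- is.na(ids)
  if (any(unknown)) {
    warning(sum(unknown), " trigger pulse(s) matched no configured level within ",
            tolerance_mV, " mV and were excluded", call. = FALSE)
  }
  ev <- data.frame(
    onset_index = onsets[!unknown],
    onset_s = (onsets[!unknown] - 1) / rate,
    amplitude_V = amps[!unknown],
    movement_id = ids[!unknown]
  )
  attr(ev, "n_unknown") <- sum(unknown)
  attr(ev, "rate_hz") <- rate
  class(ev) <- c("trigger_events", "data.frame")
  ev
}

#' Decode a pulse amplitude to a movement id
#'
#' Returns the id (1-based position) of the nearest configured level when
#' the absolute difference is within the closed tolerance, `NA` otherwise
#' (never a default id).
#'
#' @param amplitude_V measured pulse amplitude, volts.
#' @param levels_mV ascending configured levels, mV.
#' @param tolerance_mV closed tolerance, mV.
#' @return integer movement id, or `NA_integer_` on no match.
#' @export
decode_movement <- function(amplitude_V, levels_mV = seq(15, 40, by = 5),
                            tolerance_mV = 2) {
  diffs <- abs(amplitude_V * 1000 - levels_mV)
  k <- which.min(diffs)
  if (diffs[k] <= tolerance_mV) as.integer(k) else NA_integer_
}

#' Extract per-device analysis windows around trigger events
#'
#' Cuts one fixed-duration window per event and device from a preprocessed
#' recording. Event onsets detected on the native grid are mapped to the
#' processed grid by integer division of the 0-based index by the rate
#' ratio. The default 3 s window starts at the trigger onset, covering the
#' instruction, the 2 s contraction with its reaction latency, and the
#' following second. Windows that would run past the end of the recording
#' are dropped with a warning.
#'
#' @param prep a `preprocessed_recording`.
#' @param events a `trigger_events` data.frame from [detect_triggers()].
#' @param window_s window duration, seconds.
#' @param offset_s start offset relative to the trigger onset, seconds.
#' @param subject_id label stored on each window (defaults to recording
#'   metadata).
#' @return list of `epoch_window` objects; each is a list with `subject_id`,
#'   `trial_index`, `movement_id`, `device`, `samples`, `rate_hz`.
#' @export
extract_windows <- function(prep, events, window_s = 3, offset_s = 0,
                            subject_id = NULL) {
  stopifnot(inherits(prep, "preprocessed_recording"))
  if (window_s <= 0) stop("window_s must be positive", call. = FALSE)
  if (is.null(subject_id)) subject_id <- prep$metadata$subject_id %||% "S01"
  rate <- prep$rate_hz
  factor <- attr(events, "rate_hz") %||% prep$native_rate_hz
  factor <- factor / rate
  len <- round(window_s * rate)
  off <- round(offset_s * rate)
  n <- length(prep$reference_emg)
  windows <- list()
  dropped <- 0L
  for (k in seq_len(nrow(events))) {
    start <- (events$onset_index[k] - 1L) %/% factor + 1L + off
    end <- start + len - 1L
    if (start < 1L || end > n) {
      dropped <- dropped + 1L
      next
    }
    for (device in c("reference", "prototype")) {
      sig <- if (device == "reference") prep$reference_emg else prep$prototype_emg
      samples <- sig[start:end]
      if (prep$params$normalization_scope == "per_window")
        samples <- normalize_peak(samples)
      windows[[length(windows) + 1L]] <- structure(
        list(subject_id = subject_id, trial_index = k,
             movement_id = events$movement_id[k], device = device,
             samples = samples, rate_hz = rate),
        class = "epoch_window")
    }
  }
  if (dropped > 0L)
    warning(dropped, " window(s) dropped: truncated by the recording boundary",
            call. = FALSE)
  windows
}
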