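#' Preprocessing parameters
#'
#' Defaults follow standard surface-EMG practice for this validation
#' pipeline: decimation from the 2 kHz acquisition rate to 500 Hz, a
#' fourth-order Butterworth band-pass from 20 to 200 Hz applied zero-phase
#' (forward-backward, preserving trigger-relative timing), and peak
#' normalization of each full recording to the [-1, 1] range.
#'
#' @param target_rate_hz output sampling rate, Hz.
#' @param band_hz length-2 band-pass edges, Hz.
#' @param filter_order Butterworth band-pass order (must be even).
#' @param zero_phase apply the band-pass forward-backward.
#' @param normalization_scope `"per_recording"` (default) or `"per_window"`;
#'   the latter defers normalization to window extraction.
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(target_rate_hz = 500,
                              band_hz = c(20, 200),
                              filter_order = 4,
                              zero_phase = TRUE,
                              normalization_scope = c("per_recording", "per_window")) {
  normalization_scope <- match.arg(normalization_scope)
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[1] >= band_hz[2])
    stop("band_hz must be an increasing positive pair", call. = FALSE)
  if (band_hz[2] >= target_rate_hz / 2)
    stop("band_hz upper edge must lie below the target Nyquist rate", call. = FALSE)
  if (filter_order < 2 || filter_order %% 2 != 0)
    stop("filter_order must be a positive even integer", call. = FALSE)
  structure(list(target_rate_hz = target_rate_hz, band_hz = band_hz,
                 filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase),
                 normalization_scope = normalization_scope),
            class = "preprocess_params")
}

#' Reduce the sampling rate by integer decimation
#'
#' Applies a zero-phase FIR anti-alias low-pass (Hamming-windowed, order 64,
#' cutoff at 0.8 of the target Nyquist frequency) and keeps every
#' `source_rate / target_rate`-th sample. The rate ratio must be a positive
#' integer; a ratio of 1 returns the signal unchanged.
#'
#' @param x numeric signal.
#' @param source_rate,target_rate sampling rates in Hz.
#' @return decimated signal of length `ceiling(length(x) / factor)`.
#' @export
downsample <- function(x, source_rate, target_rate) {
  factor <- source_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("source_rate / target_rate must be a positive integer", call. = FALSE)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(as.numeric(x))
  cutoff <- 0.8 * (target_rate / 2) / (source_rate / 2)
  aa <- signal::fir1(64, cutoff)  # returns an Ma coefficient object
  y <- signal::filtfilt(aa, as.numeric(x))
  y[seq(1, length(y), by = factor)]
}

#' Butterworth band-pass filter
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param band length-2 band edges, Hz.
#' @param order band-pass order (even; the default 4 means a second-order
#'   prototype on each edge).
#' @param zero_phase if `TRUE` (default) the filter is applied
#'   forward-backward for zero net phase shift.
#' @return filtered signal, same length as `x`.
#' @export
bandpass <- function(x, rate, band = c(20, 200), order = 4, zero_phase = TRUE) {
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] || band[2] >= rate / 2)
    stop("need 0 < band[1] < band[2] < rate/2", call. = FALSE)
  if (order < 2 || order %% 2 != 0)
    stop("order must be a positive even integer", call. = FALSE)
  bf <- signal::butter(order / 2, band / (rate / 2), type = "pass")
  if (zero_phase) {
    as.numeric(signal::filtfilt(bf, as.numeric(x)))
  } else {
    as.numeric(signal::filter(bf, as.numeric(x)))
  }
}

#' Peak normalization to the [-1, 1] range
#'
#' Divides the signal by its maximum absolute value, `y = x / max(|x|)`, so
#' the output peak magnitude is exactly 1 and the sign pattern is preserved.
#'
#' @param x numeric signal with at least one nonzero, finite sample.
#' @return normalized signal.
#' @export
normalize_peak <- function(x) {
  m <- max(abs(x))
  if (!is.finite(m) || m == 0)
    stop("cannot normalize an all-zero (or non-finite) signal", call. = FALSE)
  x / m
}

#' Preprocess a dual-device recording
#'
#' Runs the standard chain on both EMG channels, in order: decimation to
#' `target_rate_hz`, Butterworth band-pass, peak normalization (when
#' `normalization_scope = "per_recording"`). The trigger channel is never
#' filtered, decimated or normalized: it is kept at the native rate for
#' pulse detection.
#'
#' @param recording a `dual_recording` (see [generate_session()],
#'   [read_recording()]).
#' @param params a [preprocess_params()].
#' @return object of class `preprocessed_recording` with elements
#'   `reference_emg`, `prototype_emg` (processed, at `rate_hz`), `rate_hz`,
#'   `trigger_native`, `native_rate_hz`, `params`, `metadata`.
#' @export
preprocess_recording <- function(recording, params = preprocess_params()) {
  stopifnot(inherits(recording, "dual_recording"))
  fs <- recording$sampling_rate_hz
  chan <- function(x) {
    y <- downsample(x, fs, params$target_rate_hz)
    y <- bandpass(y, params$target_rate_hz, params$band_hz,
                  params$filter_order, params$zero_phase)
    if (params$normalization_scope == "per_recording") y <- normalize_peak(y)
    y
  }
  out <- list(
    reference_emg = chan(recording$reference_emg),
    prototype_emg = chan(recording$prototype_emg),
    rate_hz = params$target_rate_hz,
    trigger_native = recording$trigger,
    native_rate_hz = fs,
    params = params,
    schedule = recording$schedule,
    metadata = recording$metadata
  )
  class(out) <- "preprocessed_recording"
  out
}
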