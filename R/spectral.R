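#' One-sided FFT magnitude spectrum
#'
#' Discrete Fourier transform of the signal, returned as the one-sided
#' magnitude with its frequency axis.
#'
#' @param x numeric signal, length >= 2.
#' @param rate sampling rate, Hz.
#' @return list with `frequency_hz` and `magnitude` (length `floor(N/2)+1`).
#' @export
fft_spectrum <- function(x, rate) {
  n <- length(x)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite samples", call. = FALSE)
  X <- stats::fft(x)
  half <- seq_len(floor(n / 2) + 1)
  list(frequency_hz = (half - 1) * rate / n, magnitude = Mod(X[half]))
}

#' Fraction of spectral power inside a band
#'
#' Periodogram-based: the ratio of summed squared FFT magnitudes at
#' frequencies inside `band` (closed interval) to the total over the
#' one-sided spectrum.
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param band length-2 band edges, Hz.
#' @return fraction in [0, 1].
#' @export
band_power_fraction <- function(x, rate, band) {
  sp <- fft_spectrum(x, rate)
  p <- sp$magnitude^2
  inside <- sp$frequency_hz >= band[1] & sp$frequency_hz <= band[2]
  sum(p[inside]) / sum(p)
}

#' Normalized cross-correlation of two equal-length signals
#'
#' At each integer lag, the Pearson correlation of the overlapping
#' segments; the zero-lag value therefore equals the ordinary Pearson
#' correlation of the full series. Positive lags mean `b` trails `a`
#' (`b` shifted right matches `a`).
#'
#' @param a,b numeric vectors of equal length.
#' @param max_lag_samples largest |lag| examined (default one quarter of
#'   the series length).
#' @return list with `lag`, `coefficient`, `peak_lag`, `peak_value`.
#' @export
cross_correlation <- function(a, b, max_lag_samples = NULL) {
  n <- length(a)
  if (length(b) != n) stop("signals must have equal length", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input: correlation undefined", call. = FALSE)
  if (is.null(max_lag_samples)) max_lag_samples <- max(1L, n %/% 4)
  lags <- seq.int(-max_lag_samples, max_lag_samples)
  coef <- vapply(lags, function(k) {
    if (k >= 0) {
      ai <- a[1:(n - k)]; bi <- b[(1 + k):n]
    } else {
      ai <- a[(1 - k):n]; bi <- b[1:(n + k)]
    }
    if (length(ai) < 3 || stats::sd(ai) == 0 || stats::sd(bi) == 0) return(NA_real_)
    stats::cor(ai, bi)
  }, numeric(1))
  best <- which.max(coef)
  list(lag = lags, coefficient = coef,
       peak_lag = lags[best], peak_value = coef[best])
}

#' Spectrogram parameters
#'
#' @param window_samples STFT window length (default 256: ~2 Hz resolution
#'   at 500 Hz).
#' @param overlap_fraction fractional window overlap in [0, 1).
#' @param taper taper shape; only `"hann"` is provided.
#' @param rate_hz sampling rate of the signal, Hz.
#' @return list of class `spectrogram_params`.
#' @export
spectrogram_params <- function(window_samples = 256, overlap_fraction = 0.5,
                               taper = c("hann"), rate_hz = 500) {
  taper <- match.arg(taper)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)", call. = FALSE)
  structure(list(window_samples = as.integer(window_samples),
                 overlap_fraction = overlap_fraction, taper = taper,
                 rate_hz = rate_hz),
            class = "spectrogram_params")
}

#' Short-time Fourier magnitude grid
#'
#' Hann-tapered STFT via `signal::specgram`; rows are frequencies, columns
#' time frames.
#'
#' @param x numeric signal, at least `window_samples` long.
#' @param params a [spectrogram_params()].
#' @return list with `magnitude` (freq x time matrix), `frequency_hz`,
#'   `time_s`.
#' @export
emg_spectrogram <- function(x, params = spectrogram_params()) {
  n <- params$window_samples
  if (length(x) < n)
    stop("signal shorter than the spectrogram window", call. = FALSE)
  overlap <- floor(params$overlap_fraction * n)
  sg <- signal::specgram(x, n = n, Fs = params$rate_hz,
                         window = signal::hanning(n), overlap = overlap)
  list(magnitude = Mod(sg$S), frequency_hz = as.numeric(sg$f),
       time_s = as.numeric(sg$t))
}

#' Normalized two-dimensional cross-correlation of spectrogram grids
#'
#' For each candidate (frequency, time) shift, the overlapping cells of
#' both grids are mean-subtracted and unit-scaled over the overlap only,
#' giving a Pearson coefficient per shift; the maximum and its shift are
#' returned. Identical grids (up to positive scaling) peak at exactly 1 at
#' shift (0, 0).
#'
#' @param grid_a,grid_b numeric matrices of identical dimensions
#'   (freq x time).
#' @param max_shift length-2 integer vector, largest |shift| examined per
#'   axis (default one quarter of each dimension).
#' @return list with `peak_value` and `peak_shift` (rows = frequency axis,
#'   columns = time axis).
#' @export
spectrogram_xcorr2d <- function(grid_a, grid_b, max_shift = NULL) {
  if (!all(dim(grid_a) == dim(grid_b)))
    stop("grids must have identical dimensions", call. = FALSE)
  nr <- nrow(grid_a); nc <- ncol(grid_a)
  if (is.null(max_shift)) max_shift <- c(max(1L, nr %/% 4), max(1L, nc %/% 4))
  best <- -Inf; best_shift <- c(0L, 0L)
  for (dr in seq.int(-max_shift[1], max_shift[1])) {
    r_a <- max(1, 1 + dr):min(nr, nr + dr)
    r_b <- r_a - dr
    for (dc in seq.int(-max_shift[2], max_shift[2])) {
      c_a <- max(1, 1 + dc):min(nc, nc + dc)
      c_b <- c_a - dc
      va <- as.vector(grid_a[r_a, c_a])
      vb <- as.vector(grid_b[r_b, c_b])
      if (length(va) < 4) next
      sa <- stats::sd(va); sb <- stats::sd(vb)
      if (sa == 0 || sb == 0) next
      r <- stats::cor(va, vb)
      if (r > best) {
        best <- r
        best_shift <- c(dr, dc)
      }
    }
  }
  if (!is.finite(best)) stop("no valid overlap with nonzero variance", call. = FALSE)
  list(peak_value = best, peak_shift = best_shift)
}

#' Coefficient of determination from a correlation coefficient
#'
#' @param r correlation coefficient in [-1, 1].
#' @return `r^2`, the explained-variance fraction.
#' @export
explained_variance <- function(r) {
  if (!is.numeric(r) || any(abs(r) > 1))
    stop("correlation coefficient must lie in [-1, 1]", call. = FALSE)
  r^2
}
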