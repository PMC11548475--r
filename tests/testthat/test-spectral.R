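test_that("FFT spectrum isolates pure tones and satisfies Parseval", {
  fs <- 500
  t <- (0:(fs - 1)) / fs
  tone <- sin(2 * pi * 50 * t)
  sp <- fft_spectrum(tone, fs)
  expect_equal(sp$frequency_hz[which.max(sp$magnitude)], 50)

  set.seed(21)
  x <- rnorm(1024)
  X <- stats::fft(x)
  expect_equal(sum(x^2), sum(Mod(X)^2) / length(x), tolerance = 1e-9)

  expect_error(fft_spectrum(numeric(0), fs), "at least two")

  # band-passed broadband content stays inside the analysis band
  y <- bandpass(rnorm(20 * fs), fs)
  expect_gte(band_power_fraction(y, fs, c(20, 200)), 0.9)
})

test_that("cross-correlation peaks at the true shift and matches Pearson at lag 0", {
  set.seed(22)
  a <- rnorm(2000)
  cc <- cross_correlation(a, a)
  expect_equal(cc$peak_lag, 0)
  expect_equal(cc$peak_value, 1)

  b <- c(rep(0, 7), a[1:(length(a) - 7)])  # a delayed by 7 samples
  cc2 <- cross_correlation(a, b, max_lag_samples = 50)
  expect_equal(cc2$peak_lag, 7)

  x <- rnorm(500); y <- rnorm(500)
  cc3 <- cross_correlation(x, y, max_lag_samples = 10)
  expect_equal(cc3$coefficient[cc3$lag == 0], stats::cor(x, y),
               tolerance = 1e-12)
  expect_true(all(abs(cc3$coefficient) <= 1 + 1e-12))

  big <- cross_correlation(rnorm(1e4), rnorm(1e4), max_lag_samples = 1)
  expect_lt(abs(big$coefficient[big$lag == 0]), 0.05)

  expect_error(cross_correlation(rep(1, 100), rnorm(100)), "zero-variance")
  expect_error(cross_correlation(rnorm(5), rnorm(6)), "equal length")
})

test_that("spectrograms concentrate energy where the signal lives", {
  fs <- 500
  p <- spectrogram_params(rate_hz = fs)
  t <- (0:(6 * fs - 1)) / fs

  sg <- emg_spectrogram(sin(2 * pi * 100 * t), p)
  peak_rows <- apply(sg$magnitude, 2, which.max)
  expect_true(all(abs(sg$frequency_hz[peak_rows] - 100) < 4))

  silent <- emg_spectrogram(numeric(3 * fs), p)
  expect_true(all(silent$magnitude == 0))

  # ridge of a 20 -> 200 Hz chirp rises monotonically with time
  chirp <- sin(2 * pi * (20 * t + (180 / (2 * max(t))) * t^2))
  sgc <- emg_spectrogram(chirp, p)
  ridge <- sgc$frequency_hz[apply(sgc$magnitude, 2, which.max)]
  expect_true(all(diff(ridge) >= 0))
  expect_error(emg_spectrogram(numeric(10), p), "shorter")
})

test_that("2-D spectrogram correlation recovers identity and shifts", {
  set.seed(23)
  g <- matrix(abs(rnorm(40 * 30)), 40, 30)
  x <- spectrogram_xcorr2d(g, g)
  expect_equal(x$peak_value, 1)
  expect_equal(x$peak_shift, c(0L, 0L))

  # positive scaling does not change the normalized peak
  x2 <- spectrogram_xcorr2d(g, 3.7 * g)
  expect_equal(x2$peak_value, 1)
  expect_equal(x2$peak_shift, c(0L, 0L))

  shifted <- cbind(g[, 4:30], matrix(abs(rnorm(40 * 3)), 40, 3))
  x3 <- spectrogram_xcorr2d(g, shifted, max_shift = c(5L, 5L))
  expect_equal(x3$peak_shift, c(0L, 3L))
  expect_gt(x3$peak_value, 0.95)

  expect_error(spectrogram_xcorr2d(g, g[, 1:10]), "identical dimensions")
})

test_that("explained variance is the squared correlation", {
  expect_equal(explained_variance(1), 1)
  expect_equal(explained_variance(0), 0)
  expect_equal(explained_variance(0.9564), 0.9564^2)
  expect_equal(round(explained_variance(0.9564), 5), 0.91470)
  expect_error(explained_variance(1.2), "\\[-1, 1\\]")
})

test_that("simulated dual-device segments correlate more in the spectrogram domain", {
  prep <- default_prep()
  ev <- default_events()
  res <- compare_devices_spectral(prep, ev)
  expect_gt(res$temporal_r0, 0.5)
  expect_equal(res$spectrogram_shift, c(0L, 0L))
  expect_gt(res$spectrogram_peak, res$temporal_r0)
  expect_equal(res$explained_variance, res$spectrogram_peak^2)
})
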