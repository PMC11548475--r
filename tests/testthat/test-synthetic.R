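test_that("schedule is balanced, correctly spaced, and seeded-reproducible", {
  cfg <- sim_config()
  set.seed(7)
  sch <- build_schedule(cfg)
  expect_equal(nrow(sch), 60)
  expect_true(all(table(sch$movement_id) == 10))
  expect_equal(sort(unique(sch$movement_id)), 1:6)
  expect_equal(diff(sch$onset_s), rep(7, 59))
  expect_equal(sch$onset_s[1], 5)

  set.seed(7)
  expect_identical(build_schedule(cfg), sch)

  cfg1 <- sim_config(n_movements = 1, reps_per_movement = 1,
                     trigger_levels_mV = 15)
  sch1 <- build_schedule(cfg1)
  expect_equal(nrow(sch1), 1)
  expect_equal(sch1$movement_id, 1L)
  expect_equal(sch1$onset_s, cfg1$rest_s)

  cfg2 <- sim_config(n_movements = 2, reps_per_movement = 3,
                     trigger_levels_mV = c(15, 20))
  set.seed(11); a <- build_schedule(cfg2)
  set.seed(11); b <- build_schedule(cfg2)
  expect_identical(a, b)
  expect_true(all(table(a$movement_id) == 3))

  expect_error(sim_config(n_movements = 0, trigger_levels_mV = numeric(0)),
               "invalid")
  expect_error(sim_config(trigger_levels_mV = c(20, 15, 25, 30, 35, 40)),
               "increasing")
})

test_that("muscle source is contraction-modulated, band-limited noise", {
  cfg <- small_config(rng_seed = 3L)
  set.seed(3)
  empty <- generate_source(data.frame(onset_s = numeric(0),
                                      movement_id = integer(0)),
                           cfg, duration_s = 5)
  # only baseline activity when nothing is scheduled
  expect_lt(sqrt(mean(empty^2)), 2 * cfg$rest_amplitude)

  set.seed(4)
  one <- data.frame(onset_s = 5, movement_id = 1L)
  src <- generate_source(one, cfg, duration_s = 12)
  fs <- cfg$sampling_rate_hz
  rms_in <- sqrt(mean(src[round(6 * fs):round(6.8 * fs)]^2))
  rms_rest <- sqrt(mean(src[round(1 * fs):round(4 * fs)]^2))
  expect_gt(rms_in / rms_rest, 10)

  # spectral content confined near the configured source band
  lo <- cfg$source_band_hz[1] / 2
  hi <- cfg$source_band_hz[2] * 1.5
  frac_in <- band_power_fraction(src, fs, c(lo, hi))
  expect_gte(frac_in, 0.95)
})

test_that("prototype channel model filters, scales, and stays linear", {
  cfg <- small_config(prototype_noise_sd = 0, prototype_gain = 2)
  fs <- cfg$sampling_rate_hz
  t <- (0:(6 * fs - 1)) / fs

  expect_equal(apply_prototype_channel(numeric(3 * fs), cfg),
               numeric(3 * fs))

  s60 <- sin(2 * pi * 60 * t)
  out60 <- apply_prototype_channel(s60, cfg)
  expect_lt(sine_amplitude(out60, 60, fs, discard_s = 2) /
              (cfg$prototype_gain * 1), 0.1)

  s110 <- sin(2 * pi * 110 * t)
  out110 <- apply_prototype_channel(s110, cfg)
  ratio <- sine_amplitude(out110, 110, fs, discard_s = 2) / cfg$prototype_gain
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)

  # linearity at zero noise
  x <- sin(2 * pi * 80 * t) + 0.3 * sin(2 * pi * 150 * t)
  expect_equal(apply_prototype_channel(3.5 * x, cfg),
               3.5 * apply_prototype_channel(x, cfg), tolerance = 1e-9)

  expect_error(small_config(prototype_lp_hz = 1500), "Nyquist")
})

test_that("trigger channel encodes movement identity as amplitude-coded pulses", {
  cfg <- sim_config()
  fs <- cfg$sampling_rate_hz
  sch <- data.frame(onset_s = c(5, 12), movement_id = c(1L, 6L))
  trig <- make_trigger_channel(sch, cfg, duration_s = 20)

  p1 <- trig[(5 * fs + 1):(5 * fs + 10)]
  expect_equal(p1, rep(0.015, 10))
  expect_equal(trig[5 * fs], 0)            # zero immediately before
  expect_equal(trig[5 * fs + 11], 0)       # and after the 5 ms pulse
  p6 <- trig[(12 * fs + 1):(12 * fs + 10)]
  expect_equal(p6, rep(0.040, 10))
  expect_equal(sum(trig != 0), 20)

  none <- make_trigger_channel(data.frame(onset_s = numeric(0),
                                          movement_id = integer(0)),
                               cfg, duration_s = 2)
  expect_true(all(none == 0))

  overlap <- data.frame(onset_s = c(5, 5.001), movement_id = c(1L, 2L))
  expect_error(make_trigger_channel(overlap, cfg, duration_s = 10),
               "overlap")
})

test_that("sessions are deterministic in the seed and respect the noiseless limit", {
  cfg <- small_config(rng_seed = 9L)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$reference_emg, b$reference_emg)
  expect_identical(a$prototype_emg, b$prototype_emg)
  expect_identical(a$trigger, b$trigger)
  expect_equal(length(a$reference_emg),
               round(session_duration_s(cfg) * cfg$sampling_rate_hz))

  quiet <- small_config(rng_seed = 9L, reference_noise_sd = 0,
                        prototype_noise_sd = 0, prototype_chain = FALSE,
                        prototype_gain = 1)
  s <- generate_session(quiet)
  expect_identical(s$reference_emg, s$prototype_emg)
})

test_that("prototype residual noise exceeds reference residual noise across seeds", {
  for (seed in 1:10) {
    lo <- generate_session(small_config(rng_seed = seed,
                                        reference_noise_sd = 0,
                                        prototype_noise_sd = 0.02,
                                        prototype_chain = FALSE))
    hi <- generate_session(small_config(rng_seed = seed,
                                        reference_noise_sd = 0,
                                        prototype_noise_sd = 0.08,
                                        prototype_chain = FALSE))
    # reference carries the bare source here, so the channel difference
    # isolates the prototype's additive noise
    v_lo <- stats::var(lo$prototype_emg - lo$reference_emg)
    v_hi <- stats::var(hi$prototype_emg - hi$reference_emg)
    expect_gt(v_hi, v_lo)
  }
})
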