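test_that("all 22 features agree with the loop-based oracle on random windows", {
  set.seed(101)
  p <- feature_params()
  for (k in 1:50) {
    x <- rnorm(16, sd = 10^runif(1, -2, 1))
    got <- suppressWarnings(feature_vector(x, p))
    want <- suppressWarnings(oracle_features(x))
    expect_equal(got, want[names(got)], tolerance = 1e-9)
  }
})

test_that("hand-computed amplitude examples hold", {
  p <- feature_params()
  x <- c(3, -4)
  a <- amplitude_features(x, p)
  expect_equal(a[["RMS"]], sqrt(12.5))
  expect_equal(a[["MAV"]], 3.5)
  expect_equal(a[["IEMG"]], 7)

  const <- rep(2.5, 20)
  a2 <- amplitude_features(const, p)
  expect_equal(a2[["RMS"]], 2.5)
  expect_equal(a2[["MAV"]], 2.5)
  expect_equal(a2[["IEMG"]], 50)
  expect_equal(a2[["VO"]], 2.5)

  expect_error(amplitude_features(3), "too short")
})

test_that("difference features follow their definitions, with epsilon guards", {
  p <- feature_params()
  d <- difference_features(rep(1, 10), p)
  expect_equal(d[["EWL"]], 0)
  expect_equal(d[["LDAMV"]], log(p$log_epsilon))
  expect_equal(d[["LDASDV"]], log(p$log_epsilon))

  d2 <- difference_features(c(0, 1, 0), p)
  expect_equal(d2[["LDAMV"]], log(1 + p$log_epsilon))
  expect_equal(d2[["LDASDV"]], log(1 + p$log_epsilon))
})

test_that("threshold counts enumerate crossings and stay within bounds", {
  p <- feature_params(fzc_threshold = 0.5, wa_threshold = 0.5)
  tc <- threshold_count_features(c(1, -1, 1, -1), p)
  expect_equal(tc[["FZC"]], 3)
  expect_equal(tc[["WA"]], 3)

  const <- rep(0.5, 8)
  tc2 <- threshold_count_features(const, feature_params())
  expect_equal(tc2[["FZC"]], 0)
  expect_equal(tc2[["WA"]], 0)
  expect_equal(tc2[["CARD"]], 0)
  expect_equal(tc2[["MYOP"]], 1)   # |0.5| >= 0.016
  tc3 <- threshold_count_features(rep(0.001, 8), feature_params())
  expect_equal(tc3[["MYOP"]], 0)

  set.seed(5)
  for (k in 1:10) {
    n <- sample(4:32, 1)
    tc <- threshold_count_features(rnorm(n), feature_params())
    expect_gte(tc[["MYOP"]], 0); expect_lte(tc[["MYOP"]], 1)
    expect_lte(tc[["CARD"]], n - 1)
    expect_lte(tc[["WA"]], n - 1)
    expect_lte(tc[["FZC"]], n - 1)
  }
})

test_that("dispersion statistics match closed forms and Gaussian kurtosis", {
  s <- statistical_features(c(1, 2, 3, 4))
  expect_equal(s[["SD"]], sqrt(5 / 3))
  expect_equal(s[["MAD"]], 1.0)
  expect_equal(s[["IQR"]], 1.5)

  set.seed(6)
  g <- statistical_features(rnorm(1e5))
  expect_gt(g[["KURT"]], 2.9)
  expect_lt(g[["KURT"]], 3.1)

  # kurtosis is invariant to affine maps; zero variance is flagged
  set.seed(7)
  x <- rnorm(50)
  k1 <- statistical_features(x)[["KURT"]]
  k2 <- statistical_features(-2 * x + 5)[["KURT"]]
  expect_equal(k1, k2, tolerance = 1e-12)
  expect_warning(z <- statistical_features(rep(1, 10)), "zero-variance")
  expect_true(is.nan(z[["KURT"]]))
})

test_that("scaling laws hold across the feature set", {
  set.seed(8)
  x <- rnorm(24)
  p0 <- feature_params(fzc_threshold = 0, wa_threshold = 0, card_threshold = 0)
  linear <- c("IEMG", "MAV", "MMAV", "MMAV2", "RMS", "VO", "SD", "MAD", "IQR")
  for (a in c(2, -3, 0.1)) {
    f1 <- suppressWarnings(feature_vector(x, p0))
    fa <- suppressWarnings(feature_vector(a * x, p0))
    expect_equal(fa[linear], abs(a) * f1[linear], tolerance = 1e-9)
    expect_equal(fa[["KURT"]], f1[["KURT"]], tolerance = 1e-9)
    expect_equal(fa[["FZC"]], f1[["FZC"]])
  }
})

test_that("the assembled vector is canonical, complete and deterministic", {
  set.seed(9)
  x <- rnorm(1500, sd = 0.2)
  v <- feature_vector(x)
  expect_length(v, 22)
  expect_identical(names(v), EMG_FEATURE_NAMES)
  expect_true(all(is.finite(v)))
  expect_identical(v, feature_vector(x))
})

test_that("featurize_windows builds a keyed table over all windows", {
  w <- default_windows()[1:10]
  ft <- suppressWarnings(featurize_windows(w))
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 10)
  expect_identical(names(ft)[5:26], EMG_FEATURE_NAMES)
  expect_false(anyDuplicated(ft[, c("subject_id", "trial_index", "device")]) > 0)
})
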