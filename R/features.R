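#' Canonical order of the 22 time-domain feature indices
#'
#' The fixed column order used throughout the package for feature vectors,
#' feature tables and concordance matrices.
#' @export
EMG_FEATURE_NAMES <- c(
  "FZC", "EWL", "EMAV", "ASM", "ASS", "CARD", "LDASDV", "LDAMV", "MYOP",
  "VO", "MMAV", "MMAV2", "IEMG", "RMS", "WA", "LD", "MAV", "MAD", "IQR",
  "KURT", "COV", "SD"
)

#' Feature-extraction parameters
#'
#' Thresholds are expressed in normalized (-1..1) signal units and follow
#' the defaults of the widely used EMG feature-extraction toolbox this
#' feature set is drawn from; all are configurable.
#'
#' @param fzc_threshold minimum step size for a counted zero crossing.
#' @param wa_threshold Willison-amplitude difference threshold.
#' @param myop_threshold myopulse amplitude threshold.
#' @param card_threshold minimum sorted-neighbour gap for cardinality.
#' @param v_order exponent of the order-v amplitude measure (VO).
#' @param log_epsilon guard added inside logarithms to avoid log(0).
#' @return list of class `feature_params`.
#' @export
feature_params <- function(fzc_threshold = 0.01, wa_threshold = 0.01,
                           myop_threshold = 0.016, card_threshold = 0.01,
                           v_order = 2, log_epsilon = 1e-10) {
  stopifnot(fzc_threshold >= 0, wa_threshold >= 0, myop_threshold >= 0,
            card_threshold >= 0, v_order > 0, log_epsilon > 0)
  structure(list(fzc_threshold = fzc_threshold, wa_threshold = wa_threshold,
                 myop_threshold = myop_threshold, card_threshold = card_threshold,
                 v_order = v_order, log_epsilon = log_epsilon),
            class = "feature_params")
}

check_window <- function(x) {
  if (length(x) < 2) stop("window too short: need at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("window contains non-finite samples", call. = FALSE)
  as.numeric(x)
}

# Piecewise exponent p_i used by EMAV, ASM and EWL: 0.75 in the central
# 0.2N <= i <= 0.8N region (1-based sample index), 0.5 in the tails.
emav_exponents <- function(n) {
  i <- seq_len(n)
  ifelse(i >= 0.2 * n & i <= 0.8 * n, 0.75, 0.5)
}

#' Amplitude-scale features
#'
#' Computes the ten amplitude-type indices of a window `x_1..x_N`:
#' \itemize{
#'   \item `IEMG` integrated EMG, sum of |x_i|; `MAV` its mean.
#'   \item `MMAV` mean absolute value with weight 1 in the central
#'     0.25N..0.75N region and 0.5 in the tails; `MMAV2` with central
#'     weight 1 and linear tail weights 4i/N (below) and 4(N-i)/N (above).
#'   \item `EMAV` mean of |x_i|^p_i with p_i = 0.75 centrally
#'     (0.2N..0.8N) and 0.5 in the tails.
#'   \item `RMS` root mean square; `VO` the order-v generalization
#'     ((mean |x|^v)^(1/v)).
#'   \item `LD` logarithm detector exp(mean log(|x_i| + eps)).
#'   \item `ASM` |sum x_i^p_i| and `ASS` |sum x_i^0.5|: fractional powers
#'     of negative samples are taken as principal complex roots and the
#'     modulus of the complex sum is returned.
#' }
#'
#' @param x numeric window, length >= 2.
#' @param params a [feature_params()].
#' @return named numeric vector of the ten features.
#' @export
amplitude_features <- function(x, params = feature_params()) {
  x <- check_window(x)
  n <- length(x)
  i <- seq_len(n)
  ax <- abs(x)
  iemg <- sum(ax)
  mav <- iemg / n

  central <- i >= 0.25 * n & i <= 0.75 * n
  w1 <- ifelse(central, 1, 0.5)
  mmav <- sum(w1 * ax) / n
  w2 <- ifelse(central, 1, ifelse(i < 0.25 * n, 4 * i / n, 4 * (n - i) / n))
  mmav2 <- sum(w2 * ax) / n

  p <- emav_exponents(n)
  emav <- sum(ax^p) / n

  rms <- sqrt(sum(x^2) / n)
  v <- params$v_order
  vo <- (sum(ax^v) / n)^(1 / v)
  ld <- exp(sum(log(ax + params$log_epsilon)) / n)

  xc <- as.complex(x)
  asm <- Mod(sum(xc^p))
  ass <- Mod(sum(xc^0.5))

  c(IEMG = iemg, MAV = mav, MMAV = mmav, MMAV2 = mmav2, EMAV = emav,
    RMS = rms, VO = vo, LD = ld, ASM = asm, ASS = ass)
}

#' First-difference features
#'
#' With differences `d_i = x_{i+1} - x_i`:
#' \itemize{
#'   \item `EWL` enhanced waveform length, sum over i = 2..N of
#'     |d_{i-1}|^p_i with the same central/tail exponents as EMAV.
#'   \item `LDAMV` log of the mean absolute difference (+ eps guard).
#'   \item `LDASDV` log of the root-mean-square difference (+ eps guard).
#' }
#'
#' @inheritParams amplitude_features
#' @return named numeric vector `EWL`, `LDAMV`, `LDASDV`.
#' @export
difference_features <- function(x, params = feature_params()) {
  x <- check_window(x)
  n <- length(x)
  d <- diff(x)
  eps <- params$log_epsilon
  p <- emav_exponents(n)[2:n]
  ewl <- sum(abs(d)^p)
  damv <- sum(abs(d)) / (n - 1)
  dasdv <- sqrt(sum(d^2) / (n - 1))
  c(EWL = ewl, LDAMV = log(damv + eps), LDASDV = log(dasdv + eps))
}

#' Threshold-count features
#'
#' \itemize{
#'   \item `FZC` adjusted zero crossings: sign changes whose step exceeds
#'     the threshold.
#'   \item `WA` Willison amplitude: count of absolute first differences at
#'     or above the threshold.
#'   \item `MYOP` myopulse percentage rate: fraction of samples with
#'     |x_i| at or above the threshold (in [0, 1]).
#'   \item `CARD` cardinality: count of sorted-neighbour gaps strictly
#'     above the threshold.
#' }
#'
#' @inheritParams amplitude_features
#' @return named numeric vector `FZC`, `WA`, `MYOP`, `CARD`.
#' @export
threshold_count_features <- function(x, params = feature_params()) {
  x <- check_window(x)
  n <- length(x)
  d <- diff(x)
  fzc <- sum(x[-n] * x[-1] < 0 & abs(d) >= params$fzc_threshold)
  wa <- sum(abs(d) >= params$wa_threshold)
  myop <- mean(abs(x) >= params$myop_threshold)
  s <- sort(x)
  card <- sum(abs(diff(s)) > params$card_threshold)
  c(FZC = fzc, WA = wa, MYOP = myop, CARD = card)
}

#' Dispersion and shape statistics
#'
#' `SD` is the sample (N-1) standard deviation; `MAD` the mean absolute
#' deviation about the mean; `IQR` the interquartile range under
#' linear-interpolation quantiles; `KURT` the (non-excess) kurtosis
#' m4 / m2^2 using 1/N central moments; `COV` the coefficient of variation
#' SD / mean. A zero-variance window makes `KURT` undefined (returned as
#' `NaN` with a warning); a near-zero mean makes `COV` numerically
#' explosive — it is computed as specified but a warning flags windows with
#' |mean| below `sqrt(log_epsilon)` (an exactly zero mean is guarded with
#' `log_epsilon` in the denominator).
#'
#' @inheritParams amplitude_features
#' @return named numeric vector `SD`, `MAD`, `IQR`, `KURT`, `COV`.
#' @export
statistical_features <- function(x, params = feature_params()) {
  x <- check_window(x)
  n <- length(x)
  m <- mean(x)
  sdev <- stats::sd(x)
  mad_m <- sum(abs(x - m)) / n
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  m2 <- sum((x - m)^2) / n
  if (m2 == 0) {
    warning("zero-variance window: kurtosis undefined", call. = FALSE)
    kurt <- NaN
  } else {
    kurt <- (sum((x - m)^4) / n) / m2^2
  }
  eps <- params$log_epsilon
  if (abs(m) < sqrt(eps))
    warning("near-zero window mean: coefficient of variation is unstable",
            call. = FALSE)
  denom <- if (m == 0) eps else m
  c(SD = sdev, MAD = mad_m, IQR = iqr, KURT = kurt, COV = sdev / denom)
}

#' Full 22-feature vector of a window
#'
#' Concatenates [threshold_count_features()], [difference_features()],
#' [amplitude_features()] and [statistical_features()] and orders the
#' result canonically ([EMG_FEATURE_NAMES]).
#'
#' @param x numeric window (or an `epoch_window`).
#' @param params a [feature_params()].
#' @return named numeric vector of length 22.
#' @export
feature_vector <- function(x, params = feature_params()) {
  if (inherits(x, "epoch_window")) x <- x$samples
  v <- c(amplitude_features(x, params), difference_features(x, params),
         threshold_count_features(x, params), statistical_features(x, params))
  v[EMG_FEATURE_NAMES]
}

#' Feature table for a set of epoch windows
#'
#' Applies [feature_vector()] to every window and assembles a long-format
#' table with one row per (subject, trial, device).
#'
#' @param windows list of `epoch_window` objects (see [extract_windows()]).
#' @param params a [feature_params()].
#' @return data.frame of class `feature_table` with key columns
#'   `subject_id`, `trial_index`, `movement_id`, `device` followed by the
#'   22 feature columns in canonical order.
#' @export
featurize_windows <- function(windows, params = feature_params()) {
  stopifnot(length(windows) > 0)
  keys <- do.call(rbind, lapply(windows, function(w) {
    data.frame(subject_id = w$subject_id, trial_index = w$trial_index,
               movement_id = w$movement_id, device = w$device,
               stringsAsFactors = FALSE)
  }))
  n_cov_flagged <- 0L
  feats <- do.call(rbind, lapply(windows, function(w) {
    withCallingHandlers(
      feature_vector(w$samples, params),
      warning = function(cnd) {
        if (grepl("near-zero window mean", conditionMessage(cnd))) {
          n_cov_flagged <<- n_cov_flagged + 1L
          invokeRestart("muffleWarning")
        }
      })
  }))
  if (n_cov_flagged > 0L)
    warning(n_cov_flagged,
            " window(s) have a near-zero mean: their COV values are unstable",
            call. = FALSE)
  out <- cbind(keys, as.data.frame(feats))
  attr(out, "n_cov_flagged") <- n_cov_flagged
  if (anyDuplicated(out[, c("subject_id", "trial_index", "device")]))
    stop("duplicate (subject, trial, device) keys in feature table", call. = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}
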