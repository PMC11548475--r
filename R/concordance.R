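#' Mean absolute percentage error between paired series
#'
#' `mape(y, yhat)` is `mean(|y_i - yhat_i| / |y_i|)` over the paired
#' windows, returned as a fraction (multiply by 100 only for display).
#' Pairs whose actual value has magnitude below `zero_tol` are excluded
#' (MAPE is undefined at zero) and the exclusion count is attached as the
#' `"n_excluded"` attribute. The denominator uses the absolute actual value
#' so that negative-valued features (e.g. the log-difference indices) do
#' not flip the error sign.
#'
#' @param actual numeric vector of reference-device values (`y`).
#' @param predicted numeric vector of prototype values (`yhat`), same length.
#' @param zero_tol pairwise exclusion threshold on `|actual|`.
#' @return scalar fraction with attribute `n_excluded`.
#' @export
mape <- function(actual, predicted, zero_tol = 1e-8) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length", call. = FALSE)
  if (length(actual) < 1) stop("need at least one pair", call. = FALSE)
  keep <- is.finite(actual) & is.finite(predicted) & abs(actual) >= zero_tol
  n_excluded <- sum(!keep)
  if (!any(keep))
    stop("all pairs excluded (near-zero or non-finite actuals): MAPE undefined",
         call. = FALSE)
  out <- mean(abs(actual[keep] - predicted[keep]) / abs(actual[keep]))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Inverted MAPE concordance
#'
#' `1 - mape(actual, predicted)`: 1 means perfect agreement, 0 no
#' similarity. Values below 0 (MAPE above 100%) are reported unclipped,
#' with a warning, so gross disagreement stays visible.
#'
#' @inheritParams mape
#' @return scalar fraction with attribute `n_excluded`.
#' @export
inverted_mape <- function(actual, predicted, zero_tol = 1e-8) {
  m <- mape(actual, predicted, zero_tol)
  out <- 1 - as.numeric(m)
  if (out < 0)
    warning("concordance below 0 (MAPE > 100%): reported unclipped", call. = FALSE)
  attr(out, "n_excluded") <- attr(m, "n_excluded")
  out
}

#' Feature-by-subject concordance matrix
#'
#' For each subject and each of the 22 features, pairs the reference-device
#' window values (actual) with the prototype values (predicted) by trial
#' index and computes the inverted MAPE. Marginal means per feature and per
#' subject and the overall mean are taken over non-missing cells.
#'
#' @param feature_table a `feature_table` (possibly spanning several
#'   subjects) from [featurize_windows()], containing both devices.
#' @param clip if `TRUE`, negative cells are clipped to 0 (default keeps
#'   them, for transparency about gross disagreement).
#' @param exclude_features optional character vector of feature names to
#'   drop from the matrix (e.g. `"COV"`, which is unstable on near-zero
#'   mean windows).
#' @param zero_tol pairwise near-zero exclusion threshold (see [mape()]).
#' @return object of class `concordance_matrix`: list with `values`
#'   (feature x subject matrix), `per_feature_mean`, `per_subject_mean`,
#'   `overall_mean`, `n_windows_used` and `n_excluded` (matrices).
#' @export
concordance_matrix <- function(feature_table, clip = FALSE,
                               exclude_features = NULL, zero_tol = 1e-8) {
  stopifnot(is.data.frame(feature_table))
  feats <- setdiff(EMG_FEATURE_NAMES, exclude_features)
  subjects <- unique(feature_table$subject_id)
  values <- matrix(NA_real_, nrow = length(feats), ncol = length(subjects),
                   dimnames = list(feats, subjects))
  n_used <- n_excl <- matrix(0L, nrow = length(feats), ncol = length(subjects),
                             dimnames = list(feats, subjects))
  for (s in subjects) {
    ref <- feature_table[feature_table$subject_id == s &
                           feature_table$device == "reference", , drop = FALSE]
    pro <- feature_table[feature_table$subject_id == s &
                           feature_table$device == "prototype", , drop = FALSE]
    if (nrow(ref) != nrow(pro) || nrow(ref) == 0) {
      warning("subject ", s, " skipped: mismatched window counts (",
              nrow(ref), " reference vs ", nrow(pro), " prototype)",
              call. = FALSE)
      next
    }
    ref <- ref[order(ref$trial_index), , drop = FALSE]
    pro <- pro[order(pro$trial_index), , drop = FALSE]
    if (!identical(ref$trial_index, pro$trial_index)) {
      warning("subject ", s, " skipped: trial indices do not pair", call. = FALSE)
      next
    }
    for (f in feats) {
      cell <- tryCatch(
        suppressWarnings(inverted_mape(ref[[f]], pro[[f]], zero_tol)),
        error = function(e) NULL)
      if (is.null(cell)) next
      values[f, s] <- if (clip) max(0, as.numeric(cell)) else as.numeric(cell)
      n_excl[f, s] <- attr(cell, "n_excluded")
      n_used[f, s] <- nrow(ref) - attr(cell, "n_excluded")
    }
  }
  structure(list(
    values = values,
    per_feature_mean = rowMeans(values, na.rm = TRUE),
    per_subject_mean = colMeans(values, na.rm = TRUE),
    overall_mean = mean(values, na.rm = TRUE),
    n_windows_used = n_used,
    n_excluded = n_excl,
    clip = clip
  ), class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf("concordance_matrix: %d features x %d subjects\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("overall mean (1 - MAPE): %.4f (%.1f%%)\n",
              x$overall_mean, 100 * x$overall_mean))
  if (any(x$n_excluded > 0))
    cat(sprintf("near-zero pairs excluded: %d\n", sum(x$n_excluded)))
  invisible(x)
}
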