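# Wavelet-statistical feature extraction: per channel, a level-5 db4
# decomposition yields 6 coefficient bands (A5, D5..D1); each band is
# summarised by 9 statistics, giving channels x 6 x 9 features per epoch
# (62 channels -> 3348 columns). Because the statistics collapse each
# variable-length band, the feature count is independent of epoch duration.

#' Per-band statistic names, in the fixed column order
#' @param percentiles Percentile probabilities used for the quantile
#'   statistics (default `c(0.25, 0.75, 0.95)`).
#' @return Character vector of statistic names.
#' @export
band_statistic_names <- function(percentiles = c(0.25, 0.75, 0.95)) {
  c("zcr", paste0("p", round(100 * percentiles)),
    "mean", "median", "sd", "var", "rms")
}

#' Summary statistics of one wavelet-coefficient band
#'
#' Returns, in fixed order: zero-crossing rate (strict sign changes divided
#' by n-1, zeros counted as positive), the requested percentiles
#' (linear-interpolation convention), mean, median, standard deviation,
#' variance and root mean square.
#'
#' @param coeffs Numeric vector of length >= 2.
#' @param percentiles Percentile probabilities (default `c(0.25, 0.75,
#'   0.95)`).
#' @return Named numeric vector of `length(percentiles) + 6` statistics.
#' @export
#' @examples
#' band_statistics(c(1, -1, 1, -1))["zcr"]   # 1
band_statistics <- function(coeffs, percentiles = c(0.25, 0.75, 0.95)) {
  n <- length(coeffs)
  if (n < 2) {
    abort("need at least 2 coefficients (rates and deviations are undefined)",
          class = "painsense_parameter_error")
  }
  s <- ifelse(coeffs >= 0, 1, -1)   # zeros counted as positive
  zcr <- sum(s[-1] != s[-n]) / (n - 1)
  q <- quantile(coeffs, probs = percentiles, names = FALSE, type = 7)
  out <- c(zcr, q, mean(coeffs), median(coeffs), sd(coeffs), var(coeffs),
           sqrt(mean(coeffs^2)))
  names(out) <- band_statistic_names(percentiles)
  out
}

#' Feature-extraction configuration
#'
#' @param wavelet Wavelet name (default `"db4"`).
#' @param level Decomposition depth (default 5).
#' @param percentiles Percentile probabilities for [band_statistics()].
#' @return A `feature_config` list.
#' @export
feature_config <- function(wavelet = "db4", level = 5L,
                           percentiles = c(0.25, 0.75, 0.95)) {
  structure(list(wavelet = wavelet, level = as.integer(level),
                 percentiles = percentiles),
            class = "feature_config")
}

#' Extract wavelet-statistical features from an epoch set
#'
#' For every epoch and channel, decomposes the signal with
#' [dwt_decompose()] and summarises each of the `level + 1` bands with
#' [band_statistics()]. One row per epoch; the column count
#' (`channels x bands x statistics`) does not depend on epoch duration.
#'
#' @param epochs An `eeg_epochs` object (preprocessed).
#' @param config A [feature_config()].
#' @return A tibble with columns `epoch` (row index), `rating`, and one
#'   column per feature named `<channel>_<band>_<statistic>`.
#' @export
extract_features <- function(epochs, config = feature_config()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  min_len <- dwt_min_length(config$wavelet, config$level)
  short <- which(vapply(epochs$signals, ncol, 0L) < min_len)
  if (length(short) > 0) {
    abort(sprintf("epoch(s) %s are shorter than the DWT minimum of %d samples",
                  paste(short, collapse = ", "), min_len),
          class = "painsense_length_error")
  }
  nch <- nrow(epochs$signals[[1]])
  stat_names <- band_statistic_names(config$percentiles)
  band_names <- c(paste0("A", config$level), paste0("D", config$level:1))
  feat_names <- as.vector(t(outer(
    epochs$channel_names,
    as.vector(t(outer(band_names, stat_names, paste, sep = "_"))),
    paste, sep = "_")))
  rows <- purrr::map(epochs$signals, function(sig) {
    per_ch <- lapply(seq_len(nch), function(ch) {
      wb <- dwt_decompose(sig[ch, ], config$wavelet, config$level)
      unlist(lapply(wb$bands, band_statistics,
                    percentiles = config$percentiles), use.names = FALSE)
    })
    unlist(per_ch, use.names = FALSE)
  })
  X <- do.call(rbind, rows)
  colnames(X) <- feat_names
  if (anyNA(X) || any(!is.finite(X))) {
    abort("feature matrix contains NA/Inf values", class = "painsense_value_error")
  }
  dplyr::bind_cols(
    tibble(epoch = seq_along(epochs$signals), rating = epochs$ratings),
    as_tibble(X))
}

#' Split a feature tibble into a numeric matrix and metadata
#'
#' Convenience accessor: everything except `epoch`, `rating`, `label` and
#' `variant` columns is treated as a feature.
#'
#' @param features A tibble from [extract_features()] or
#'   [generate_feature_table()].
#' @return List with `x` (numeric matrix) and `meta` (tibble of the
#'   non-feature columns).
#' @export
feature_matrix <- function(features) {
  meta_cols <- intersect(c("epoch", "rating", "label", "variant"),
                         names(features))
  x <- as.matrix(features[setdiff(names(features), meta_cols)])
  list(x = x, meta = features[meta_cols])
}
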