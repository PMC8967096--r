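#' Common amplitude threshold across medication conditions
#'
#' The burst threshold applied to both conditions of a hemisphere: the mean
#' of the OFF and ON envelope percentiles.
#'
#' @param envelope_off,envelope_on per-condition envelope vectors.
#' @param percentile percentile level (the standard grid is 55, 57, ..., 99).
#' @return Scalar threshold.
#' @export
common_threshold <- function(envelope_off, envelope_on, percentile) {
  if (!length(envelope_off) || !length(envelope_on)) stop("empty envelope")
  (stats::quantile(envelope_off, percentile / 100, names = FALSE, type = 7) +
   stats::quantile(envelope_on, percentile / 100, names = FALSE, type = 7)) / 2
}

#' The standard percentile grid
#'
#' 55th to 99th percentile in steps of 2 (23 threshold models).
#'
#' @return Integer vector of percentile levels.
#' @export
percentile_grid <- function() seq(55L, 99L, by = 2L)

#' Detect bursts by amplitude thresholding
#'
#' Maximal runs where the envelope is `>=` the threshold; no minimum-duration
#' filter is applied.
#'
#' @param envelope numeric envelope vector (one session).
#' @param threshold scalar threshold.
#' @return 2-column matrix of half-open sample intervals `[start, end)`
#'   (0-based).
#' @export
detect_bursts <- function(envelope, threshold) {
  stopifnot_finite(envelope, "envelope")
  r <- rle(envelope >= threshold)
  ends <- cumsum(r$lengths)
  starts <- c(0, head(ends, -1))
  cbind(starts, ends)[r$values, , drop = FALSE]
}

#' Burst summary features
#'
#' Burst rate (bursts/s), mean duration (s), and relative duration-binned
#' counts over the same 10 bins as the state features.
#'
#' @param intervals burst intervals from [detect_bursts()].
#' @param n_samples session length in samples.
#' @param fs sampling rate in Hz.
#' @return A list with `rate`, `mean_duration`, `relative_counts` (length-10,
#'   all `NA` when there are no bursts) and `fo` (fraction of time in burst).
#' @export
burst_features <- function(intervals, n_samples, fs = 100) {
  dur_total <- n_samples / fs
  if (nrow(intervals) == 0)
    return(list(rate = 0, mean_duration = NA_real_,
                relative_counts = stats::setNames(rep(NA_real_, 10), duration_bin_labels()),
                fo = 0))
  d <- (intervals[, 2] - intervals[, 1]) / fs
  counts <- tabulate(findInterval(d, duration_bin_edges()), nbins = 10)
  list(rate = nrow(intervals) / dur_total,
       mean_duration = mean(d),
       relative_counts = stats::setNames(counts / sum(counts), duration_bin_labels()),
       fo = sum(d) / dur_total)
}

#' Tidy threshold-burst feature table for one percentile model
#'
#' For each hemisphere and band: one common threshold (mean of the OFF and
#' ON envelope percentiles, computed per hemisphere), burst detection per
#' condition, and the burst features, in the same tidy layout as
#' [feature_table()] with ON-OFF delta rows.
#'
#' @param envelopes_by_session named list (`"<hemisphere> <condition>"`) of
#'   per-session envelope matrices (samples x bands).
#' @param manifest data.frame with `hemisphere`, `condition` per session in
#'   the same order/naming as the list.
#' @param percentile percentile level.
#' @param fs sampling rate in Hz.
#' @return Tidy data.frame: hemisphere, condition, level = "band", unit =
#'   band, feature, value.
#' @export
threshold_feature_table <- function(envelopes_by_session, manifest, percentile, fs = 100) {
  hemis <- unique(manifest$hemisphere)
  feat_names <- c("rate", "mean_duration", "fo",
                  paste0("relbursts_", duration_bin_labels()))
  hv <- character(0); cv <- character(0); uv <- character(0)
  fv <- character(0); vv <- numeric(0)
  for (h in hemis) {
    e_off <- envelopes_by_session[[paste(h, "OFF")]]
    e_on <- envelopes_by_session[[paste(h, "ON")]]
    for (b in colnames(e_off)) {
      thr <- common_threshold(e_off[, b], e_on[, b], percentile)
      for (cond in c("OFF", "ON")) {
        env <- if (cond == "OFF") e_off[, b] else e_on[, b]
        bf <- burst_features(detect_bursts(env, thr), length(env), fs)
        hv <- c(hv, rep(h, 13)); cv <- c(cv, rep(cond, 13))
        uv <- c(uv, rep(b, 13)); fv <- c(fv, feat_names)
        vv <- c(vv, bf$rate, bf$mean_duration, bf$fo, as.numeric(bf$relative_counts))
      }
    }
  }
  tab <- data.frame(hemisphere = hv, condition = cv, level = "band", unit = uv,
                    feature = fv, value = vv, stringsAsFactors = FALSE)
  rbind(tab, delta_rows(tab))
}
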