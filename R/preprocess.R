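#' Standardize a raw session for state modelling
#'
#' Zero-phase Butterworth bandpass (forward-backward, order 4), resampling to
#' `fs_out` (with an additional zero-phase anti-alias lowpass at the output
#' Nyquist when downsampling), and per-session z-normalization of every
#' channel.
#'
#' @param session a `session` object (`signal` samples x channels, `fs`, ...).
#' @param band numeric length-2 passband in Hz (default 2-48).
#' @param fs_out output sampling rate in Hz (default 100).
#' @return A `session` object at `fs_out` with z-normalized channels.
#' @export
preprocess_session <- function(session, band = c(2, 48), fs_out = 100) {
  stopifnot(inherits(session, "session"))
  sig <- as.matrix(session$signal)
  if (!all(is.finite(sig))) stop("session signal must be finite")
  fs <- session$fs
  if (fs < 2 * band[2]) stop("sampling rate ", fs, " Hz below Nyquist requirement for ", band[2], " Hz")
  sds <- apply(sig, 2, stats::sd)
  if (any(sds == 0)) stop("constant channel (zero variance) cannot be z-normalized")

  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  out <- apply(sig, 2, function(x) signal::filtfilt(bf, x))

  if (fs != fs_out) {
    if (fs > 2 * fs_out) {
      # extra zero-phase guard against content between the passband edge and
      # the original Nyquist aliasing into band after resampling
      lp <- signal::butter(4, (fs_out / 2) / (fs / 2), type = "low")
      out <- apply(out, 2, function(x) signal::filtfilt(lp, x))
    }
    r <- ratio_approx(fs_out / fs)
    out <- apply(out, 2, function(x) signal::resample(x, r$p, r$q))
  }
  out <- apply(out, 2, function(x) (x - mean(x)) / stats::sd(x))
  structure(list(signal = out, fs = fs_out, hemisphere_id = session$hemisphere_id,
                 condition = session$condition, channel_labels = session$channel_labels),
            class = "session")
}

# Small-denominator rational approximation of a resampling factor.
ratio_approx <- function(x, max_den = 10000) {
  for (q in 1:max_den) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(list(p = as.integer(round(p)), q = q))
  }
  stop("cannot express resampling ratio ", x, " as a small rational")
}

#' Select the analysis contact pair
#'
#' Returns the channel with the highest mean Welch power in the beta band,
#' averaged over the OFF and ON conditions. Ties break to the lowest index.
#'
#' @param session_off,session_on matching `session` objects.
#' @param beta_band band used for selection, default 13-35 Hz (low + high beta).
#' @return Integer channel index (1-based).
#' @export
select_contact_pair <- function(session_off, session_on, beta_band = c(13, 35)) {
  if (ncol(session_off$signal) != ncol(session_on$signal))
    stop("channel counts differ between conditions")
  pow <- sapply(seq_len(ncol(session_off$signal)), function(ch) {
    mean(c(band_power(session_off$signal[, ch], session_off$fs, beta_band[1], beta_band[2]),
           band_power(session_on$signal[, ch], session_on$fs, beta_band[1], beta_band[2])))
  })
  which.max(pow) # which.max ties -> lowest index
}

#' Truncate OFF and ON sessions to a common duration
#'
#' The longer session of the pair is truncated to the shorter, so both
#' medication conditions contribute equal data per hemisphere.
#'
#' @param session_off,session_on `session` objects at the same sampling rate.
#' @return A list with the two (possibly truncated) sessions.
#' @export
match_durations <- function(session_off, session_on) {
  n <- min(nrow(session_off$signal), nrow(session_on$signal))
  trunc1 <- function(s) {
    s$signal <- s$signal[seq_len(n), , drop = FALSE]
    s
  }
  list(OFF = trunc1(session_off), ON = trunc1(session_on))
}

#' Concatenate single-channel sessions with boundary bookkeeping
#'
#' Signals are concatenated in the given (manifest) order; the half-open
#' sample range of each session is recorded so that downstream feature
#' extraction never counts a state visit or transition across a session
#' boundary.
#'
#' @param sessions list of single-channel `session` objects at 100 Hz.
#' @return An object of class `concat_lfp`: `x` (numeric vector), `fs`, and
#'   `boundaries` (data.frame hemisphere, condition, start, end with 0-based
#'   half-open sample ranges).
#' @export
concatenate_sessions <- function(sessions) {
  if (length(sessions) == 0) stop("no sessions to concatenate")
  fs <- unique(vapply(sessions, function(s) s$fs, 0))
  if (length(fs) != 1) stop("mixed sampling rates cannot be concatenated")
  lens <- vapply(sessions, function(s) nrow(as.matrix(s$signal)), 0L)
  ends <- cumsum(lens)
  starts <- c(0, head(ends, -1))
  x <- unlist(lapply(sessions, function(s) as.numeric(s$signal[, 1])), use.names = FALSE)
  boundaries <- data.frame(
    hemisphere = vapply(sessions, function(s) s$hemisphere_id, ""),
    condition = vapply(sessions, function(s) s$condition, ""),
    start = starts, end = ends, stringsAsFactors = FALSE)
  rownames(boundaries) <- NULL
  structure(list(x = x, fs = fs, boundaries = boundaries), class = "concat_lfp")
}

#' @export
print.concat_lfp <- function(x, ...) {
  cat(sprintf("Concatenated LFP: %d samples @ %g Hz, %d sessions\n",
              length(x$x), x$fs, nrow(x$boundaries)))
  invisible(x)
}

#' Preprocess and concatenate a cohort
#'
#' Runs the full standardization path on a simulated or loaded cohort:
#' per-session bandpass/resample/z-normalize, contact-pair selection on the
#' OFF+ON average beta power, OFF/ON duration matching, and concatenation.
#'
#' @param cohort result of [simulate_cohort()] or [read_cohort()].
#' @param band,fs_out passed to [preprocess_session()].
#' @return A `concat_lfp` object; the selected channel per hemisphere is
#'   attached as attribute `"selected_channel"`.
#' @export
preprocess_cohort <- function(cohort, band = c(2, 48), fs_out = 100) {
  singles <- list()
  selected <- integer(0)
  for (h in names(cohort$sessions)) {
    off <- preprocess_session(cohort$sessions[[h]]$OFF, band, fs_out)
    on <- preprocess_session(cohort$sessions[[h]]$ON, band, fs_out)
    ch <- select_contact_pair(off, on)
    selected[h] <- ch
    keep1 <- function(s) {
      s$signal <- s$signal[, ch, drop = FALSE]
      # re-normalize the retained channel (duration matching below keeps it near z)
      s$signal[, 1] <- (s$signal[, 1] - mean(s$signal[, 1])) / stats::sd(s$signal[, 1])
      s
    }
    pair <- match_durations(keep1(off), keep1(on))
    singles[[paste(h, "OFF")]] <- pair$OFF
    singles[[paste(h, "ON")]] <- pair$ON
  }
  out <- concatenate_sessions(singles)
  attr(out, "selected_channel") <- selected
  out
}
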