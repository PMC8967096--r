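#' Band-limited Hilbert envelopes
#'
#' Per band: zero-phase Butterworth bandpass at the band edges, then the
#' analytic-signal magnitude. Envelopes are computed per session segment,
#' never across boundaries.
#'
#' @param x preprocessed 1-D signal (numeric vector) or `concat_lfp`.
#' @param fs sampling rate in Hz (taken from `x` when it is a `concat_lfp`).
#' @param bands data.frame as from [default_bands()].
#' @param boundaries optional data.frame of half-open 0-based segment ranges.
#' @return A matrix `length(x)` x `nrow(bands)` of instantaneous amplitudes,
#'   columns named by band.
#' @export
band_envelopes <- function(x, fs = 100, bands = default_bands(), boundaries = NULL) {
  if (inherits(x, "concat_lfp")) {
    boundaries <- boundaries %||% x$boundaries
    fs <- x$fs
    x <- x$x
  }
  if (any(bands$f_hi >= fs / 2)) stop("band above the Nyquist frequency")
  if (is.null(boundaries)) boundaries <- data.frame(start = 0, end = length(x))
  env <- matrix(0, length(x), nrow(bands), dimnames = list(NULL, bands$band))
  for (b in seq_len(nrow(bands))) {
    bf <- signal::butter(4, c(bands$f_lo[b], bands$f_hi[b]) / (fs / 2), type = "pass")
    for (s in seq_len(nrow(boundaries))) {
      idx <- (boundaries$start[s] + 1):boundaries$end[s]
      env[idx, b] <- hilbert_envelope(signal::filtfilt(bf, x[idx]))
    }
  }
  env
}

#' Ascribe HMM states to frequency bands
#'
#' Each state's hard (0/1) time course is correlated (zero-lag Pearson) with
#' the four band-limited Hilbert envelopes. Bands with a positive
#' correlation are the candidates: with none the state is background, with
#' exactly one it is assigned to that band, and with two or more the two
#' most positive correlations must both be low-frequency (theta, alpha) or
#' both high-frequency (low beta, high beta) for the state to be assigned
#' to the band with the highest correlation -- otherwise it is background.
#' (Restricting the two-most-positive test to positive candidates keeps a
#' state with a single clear positive correlation from being discarded as a
#' straddle against a noise-level negative one.) Several states may share a
#' band. A state whose course is constant (never or always active) is
#' assigned background with a degeneracy flag.
#'
#' @param model fitted `hmm_model` (its `path` and `time_index` are used), or
#'   an integer state path when `time_index` is given.
#' @param envelopes envelope matrix from [band_envelopes()] over the signal
#'   timeline; rows are matched to states via the model's `time_index`.
#' @param use_posterior correlate posterior probabilities instead of the
#'   hard 0/1 course.
#' @return An object of class `band_map`: data.frame with `state`, `band`,
#'   and the four correlations `r_theta`, `r_alpha`, `r_low_beta`,
#'   `r_high_beta`, plus a `degenerate` flag.
#' @export
assign_bands <- function(model, envelopes, use_posterior = FALSE) {
  stopifnot(inherits(model, "hmm_model"))
  env <- envelopes[model$time_index + 1, , drop = FALSE]
  bands <- colnames(env)
  out <- data.frame(state = seq_len(model$K), band = "background",
                    stringsAsFactors = FALSE)
  rmat <- matrix(NA_real_, model$K, length(bands),
                 dimnames = list(NULL, paste0("r_", bands)))
  degenerate <- logical(model$K)
  for (k in seq_len(model$K)) {
    course <- if (use_posterior) model$gamma[, k] else as.numeric(model$path == k)
    if (stats::sd(course) == 0) {
      degenerate[k] <- TRUE
      next
    }
    r <- as.numeric(stats::cor(course, env))
    rmat[k, ] <- r
    out$band[k] <- band_rule(r, bands)
  }
  out <- cbind(out, rmat)
  out$degenerate <- degenerate
  class(out) <- c("band_map", "data.frame")
  out
}

#' The band-assignment decision rule
#'
#' Maps one state's envelope-correlation vector to a band label (or
#' `"background"`); see [assign_bands()] for the rule.
#'
#' @param r correlation of the state's time course with each band envelope.
#' @param bands band names aligned with `r`.
#' @return A single band name or `"background"`.
#' @export
band_rule <- function(r, bands = c("theta", "alpha", "low_beta", "high_beta")) {
  low <- c("theta", "alpha")
  high <- c("low_beta", "high_beta")
  pos <- which(r > 0)
  if (length(pos) == 0) return("background")
  if (length(pos) == 1) return(bands[pos])
  top2 <- bands[order(r, decreasing = TRUE)[1:2]]
  if (all(top2 %in% low) || all(top2 %in% high)) bands[which.max(r)] else "background"
}

#' Ascribe states of a gamma-band HMM run
#'
#' For the secondary gamma analysis (HMM run on 55-95 Hz filtered data) a
#' state is assigned `"gamma"` when its course correlates positively with
#' the 60-90 Hz envelope, else background.
#'
#' @param model fitted `hmm_model`.
#' @param gamma_envelope numeric vector, the 60-90 Hz Hilbert envelope on the
#'   signal timeline.
#' @return A `band_map` data.frame with `state`, `band`, `r_gamma`.
#' @export
assign_gamma_band <- function(model, gamma_envelope) {
  env <- gamma_envelope[model$time_index + 1]
  out <- data.frame(state = seq_len(model$K), band = "background",
                    r_gamma = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(model$K)) {
    course <- as.numeric(model$path == k)
    if (stats::sd(course) == 0) {
      out$degenerate[k] <- TRUE
      next
    }
    out$r_gamma[k] <- stats::cor(course, env)
    if (out$r_gamma[k] > 0) out$band[k] <- "gamma"
  }
  class(out) <- c("band_map", "data.frame")
  out
}
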