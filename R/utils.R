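#' @useDynLib lfpstates, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm runif rpois rgamma rmultinom quantile median sd
#'   var cor complete.cases p.adjust aggregate setNames na.omit
#' @importFrom utils head tail write.csv read.csv write.table read.table
#'   packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one root seed; named substreams
#' (per hemisphere, condition, restart, ...) are derived with a rolling hash
#' so that independent components draw from independent, reproducible streams.
#'
#' @param seed integer root seed.
#' @param ... further tags (coerced to character) identifying the substream.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(tags)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Hann window of length n (periodic=FALSE, symmetric taper).
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Amplitude envelope via the analytic signal
#'
#' Magnitude of the analytic signal (FFT method): the negative-frequency half
#' of the spectrum is zeroed, positive frequencies doubled.
#'
#' @param x real numeric vector.
#' @return Numeric vector of the same length, the instantaneous amplitude.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Welch power spectral density
#'
#' Hann-tapered, overlapping-segment averaged periodogram.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nfft segment length in samples.
#' @param overlap fraction of segment overlap.
#' @return A list with `freq` (Hz) and `power` (density) vectors.
#' @export
welch_psd <- function(x, fs, nfft = 256, overlap = 0.5) {
  n <- length(x)
  nfft <- min(nfft, n)
  step <- max(1, floor(nfft * (1 - overlap)))
  starts <- seq(1, n - nfft + 1, by = step)
  w <- hann_window(nfft)
  u <- sum(w^2)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / (length(starts) * u * fs)
  nh <- floor(nfft / 2)
  list(freq = (0:nh) * fs / nfft, power = p[1:(nh + 1)])
}

# Mean Welch power within [f_lo, f_hi].
band_power <- function(x, fs, f_lo, f_hi, nfft = 256) {
  ps <- welch_psd(x, fs, nfft = nfft)
  sel <- ps$freq >= f_lo & ps$freq <= f_hi
  mean(ps$power[sel])
}

# --- half-open sample-interval helpers (0-based, [start, end)) ----------------

# Merge overlapping/touching intervals. m: 2-col matrix (start, end).
merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(matrix(numeric(0), 0, 2))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- matrix(0, nrow(m), 2)
  j <- 1
  out[1, ] <- m[1, ]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    if (m[i, 1] <= out[j, 2]) {
      out[j, 2] <- max(out[j, 2], m[i, 2])
    } else {
      j <- j + 1
      out[j, ] <- m[i, ]
    }
  }
  out[seq_len(j), , drop = FALSE]
}

# Clip intervals to [0, n) and drop empties.
clip_intervals <- function(m, n) {
  if (nrow(m) == 0) return(m)
  m[, 1] <- pmax(m[, 1], 0)
  m[, 2] <- pmin(m[, 2], n)
  m[m[, 2] > m[, 1], , drop = FALSE]
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
}
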