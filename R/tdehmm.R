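#' Time-delay embed a concatenated signal
#'
#' Row `t` of the embedding holds `x[t-L .. t+L]`; rows are emitted only for
#' interior time points of each session segment, so no embedded row spans a
#' session boundary. The absolute (0-based) sample index of each row's
#' center is recorded for mapping posteriors back to signal time.
#'
#' @param x numeric vector, or a `concat_lfp` object.
#' @param L number of lags either side (window is `2L + 1` samples).
#' @param boundaries optional data.frame of half-open 0-based sample ranges
#'   (`start`, `end`); defaults to one segment covering `x`.
#' @return An object of class `tde_data`: `Y` (T x (2L+1) matrix), `L`,
#'   `time_index` (0-based center samples), `seg_start`/`seg_end` (0-based
#'   half-open row ranges per segment), and the segment table.
#' @export
embed_delay <- function(x, L, boundaries = NULL) {
  if (inherits(x, "concat_lfp")) {
    boundaries <- boundaries %||% x$boundaries
    x <- x$x
  }
  stopifnot(L >= 1)
  if (is.null(boundaries))
    boundaries <- data.frame(start = 0, end = length(x))
  d <- 2 * L + 1
  rows <- list()
  times <- list()
  n_rows <- integer(nrow(boundaries))
  for (s in seq_len(nrow(boundaries))) {
    a <- boundaries$start[s]
    b <- boundaries$end[s]
    if (b - a < d) stop("segment ", s, " shorter than the embedding window (", d, " samples)")
    centers <- (a + L):(b - L - 1)          # 0-based center samples
    idx <- outer(centers + 1, -L:L, "+")    # 1-based into x
    rows[[s]] <- matrix(x[idx], nrow = length(centers))
    times[[s]] <- centers
    n_rows[s] <- length(centers)
  }
  seg_end <- cumsum(n_rows)
  seg_start <- c(0, head(seg_end, -1))
  structure(list(Y = do.call(rbind, rows), L = L,
                 time_index = unlist(times, use.names = FALSE),
                 seg_start = seg_start, seg_end = seg_end,
                 boundaries = boundaries),
            class = "tde_data")
}

#' HMM fitting configuration
#'
#' @param K number of states (>= 2).
#' @param L number of embedding lags either side (>= 1).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change declaring convergence.
#' @param n_restarts random restarts; the best final log-likelihood wins.
#' @param seed integer seed controlling initialization.
#' @param eps diagonal covariance regularizer.
#' @param pathing `"argmax"` (per-sample argmax of the posteriors, default)
#'   or `"viterbi"` for the hard state time course.
#' @return A list of class `hmm_config`.
#' @export
hmm_config <- function(K, L, max_iter = 30, tol = 1e-4, n_restarts = 5,
                       seed = 1L, eps = 1e-6, pathing = c("argmax", "viterbi")) {
  stopifnot(K >= 2, L >= 1, tol > 0)
  structure(list(K = as.integer(K), L = as.integer(L), max_iter = as.integer(max_iter),
                 tol = tol, n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 eps = eps, pathing = match.arg(pathing)),
            class = "hmm_config")
}

# Random-responsibility initialization: contiguous blocks are softly assigned
# to random states so initial covariances differ by sampling variability.
init_hmm_params <- function(Y, seg_start, seg_end, K, eps, seed, block = 50) {
  set.seed(seed)
  T_ <- nrow(Y)
  d <- ncol(Y)
  n_blocks <- ceiling(T_ / block)
  lab <- rep(sample.int(K, n_blocks, replace = TRUE), each = block)[seq_len(T_)]
  gamma <- matrix(0.1 / (K - 1), T_, K)
  gamma[cbind(seq_len(T_), lab)] <- 0.9
  Sigma <- array(0, c(d, d, K))
  for (k in 1:K) {
    w <- gamma[, k]
    Sk <- crossprod(Y * sqrt(w)) / sum(w)
    diag(Sk) <- diag(Sk) + eps + 1e-8
    Sigma[, , k] <- (Sk + t(Sk)) / 2
  }
  A <- matrix(0.1 / (K - 1), K, K)
  diag(A) <- 0.9
  list(A = A, pi = rep(1 / K, K), Sigma = Sigma)
}

#' Fit a time-delay embedded HMM
#'
#' Baum-Welch EM with zero-mean full-covariance Gaussian emissions, run
#' segment-aware over the embedded data (forward-backward per session
#' segment, sufficient statistics pooled). The best of `n_restarts` seeded
#' random initializations by final log-likelihood is returned. Covariances
#' are regularized by adding `eps` to the diagonal. Non-convergence within
#' `max_iter` and degenerate states (occupancy below 10 samples) set flags
#' on the returned model rather than raising errors.
#'
#' @param tde a `tde_data` object from [embed_delay()], or a numeric matrix
#'   (treated as a single segment).
#' @param config an [hmm_config()]. `config$L` must match the embedding.
#' @return An object of class `hmm_model`: transition matrix `A`, initial
#'   distribution `pi`, covariance array `Sigma`, posteriors `gamma`, hard
#'   `path`, `loglik`, `loglik_trace`, flags, and the embedding bookkeeping.
#' @export
fit_hmm <- function(tde, config) {
  if (is.matrix(tde))
    tde <- structure(list(Y = tde, L = (ncol(tde) - 1) / 2,
                          time_index = seq_len(nrow(tde)) - 1,
                          seg_start = 0, seg_end = nrow(tde),
                          boundaries = data.frame(start = 0, end = nrow(tde))),
                     class = "tde_data")
  stopifnot(inherits(config, "hmm_config"))
  K <- config$K
  d <- ncol(tde$Y)
  if (nrow(tde$Y) <= K * d) stop("not enough embedded rows (", nrow(tde$Y), ") for K*(2L+1) parameters")

  # short-run restart scheme: each seeded initialization gets a few EM
  # iterations, then the best by log-likelihood continues to max_iter
  best <- NULL
  short_iter <- if (config$n_restarts > 1) min(4L, config$max_iter) else config$max_iter
  for (r in seq_len(config$n_restarts)) {
    init <- init_hmm_params(tde$Y, tde$seg_start, tde$seg_end, K, config$eps,
                            seed = derive_seed(config$seed, "restart", r))
    fit <- hmm_em_cpp(tde$Y, tde$seg_start, tde$seg_end,
                      init$A, init$pi, init$Sigma,
                      short_iter, config$tol, config$eps)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (config$n_restarts > 1 && !isTRUE(best$converged)) {
    cont <- hmm_em_cpp(tde$Y, tde$seg_start, tde$seg_end,
                       best$A, as.numeric(best$pi), best$Sigma,
                       config$max_iter - short_iter, config$tol, config$eps)
    cont$loglik_trace <- c(head(best$loglik_trace, -1), cont$loglik_trace)
    best <- cont
  }

  model <- structure(list(
    K = K, L = tde$L, A = best$A, pi = as.numeric(best$pi), Sigma = best$Sigma,
    gamma = best$gamma, loglik = best$loglik,
    loglik_trace = as.numeric(best$loglik_trace),
    converged = isTRUE(best$converged),
    degenerate_states = which(as.numeric(best$occupancy) < 10),
    config = config,
    time_index = tde$time_index, seg_start = tde$seg_start,
    seg_end = tde$seg_end, boundaries = tde$boundaries),
    class = "hmm_model")
  model$path <- hard_path(model, tde)
  model
}

# Hard state time course: per-sample argmax of gamma (ties -> lower index)
# or Viterbi, per the config.
hard_path <- function(model, tde) {
  if (model$config$pathing == "viterbi") {
    viterbi_path(model, tde)
  } else {
    max.col(model$gamma, ties.method = "first")
  }
}

#' Decode new (or full) data under a fitted model
#'
#' One exact E-step under the model's parameters: posteriors, hard path and
#' log-likelihood for the given embedded data. Used to fit on a subset of
#' sessions and decode the full cohort.
#'
#' @param model a fitted `hmm_model`.
#' @param tde a `tde_data` object with the same `L`.
#' @return The model with `gamma`, `path`, `loglik` and bookkeeping replaced
#'   by the decoded data's.
#' @export
decode_states <- function(model, tde) {
  stopifnot(inherits(model, "hmm_model"), inherits(tde, "tde_data"))
  if (ncol(tde$Y) != 2 * model$L + 1) stop("embedding dimension mismatch")
  es <- hmm_estep_cpp(tde$Y, tde$seg_start, tde$seg_end, model$A, model$pi, model$Sigma)
  model$gamma <- es$gamma
  model$loglik <- es$loglik
  model$time_index <- tde$time_index
  model$seg_start <- tde$seg_start
  model$seg_end <- tde$seg_end
  model$boundaries <- tde$boundaries
  model$path <- hard_path(model, tde)
  model
}

#' Exact marginal posteriors by the forward-backward algorithm
#'
#' Scaling-stable forward-backward for given per-state observation
#' log-densities; exposed mainly so the recursion can be validated against
#' brute-force path enumeration.
#'
#' @param A K x K row-stochastic transition matrix.
#' @param pi length-K initial distribution.
#' @param log_dens T x K matrix of per-state observation log-densities.
#' @return A list with `gamma` (T x K posteriors), `xi_sum` (summed pairwise
#'   posteriors) and `loglik`.
#' @export
forward_backward <- function(A, pi, log_dens) {
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-8)) stop("A must be row-stochastic")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) stop("pi must be a distribution")
  fb_cpp(as.matrix(log_dens), A, pi)
}

#' Most probable joint state path (Viterbi)
#'
#' `viterbi_decode()` is the plain decoder for given log-densities (one
#' segment unless ranges are supplied); `viterbi_path()` applies it to a
#' fitted model and its embedded data.
#'
#' @param A,pi transition matrix and initial distribution.
#' @param log_dens T x K matrix of per-state observation log-densities.
#' @param seg_start,seg_end 0-based half-open row ranges per segment.
#' @return Integer vector of 1-based state indices.
#' @export
viterbi_decode <- function(A, pi, log_dens, seg_start = 0, seg_end = nrow(log_dens)) {
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-8)) stop("A must be row-stochastic")
  as.integer(viterbi_cpp(as.matrix(log_dens), seg_start, seg_end, A, pi)) + 1L
}

#' @rdname viterbi_decode
#' @param model fitted `hmm_model`.
#' @param tde the embedded data (`tde_data`) to decode.
#' @export
viterbi_path <- function(model, tde) {
  log_dens <- gauss_logdens_cpp(tde$Y, model$Sigma)
  viterbi_decode(model$A, model$pi, log_dens, tde$seg_start, tde$seg_end)
}

#' Per-state power spectra from the embedded-space covariance
#'
#' Each state's `(2L+1)`-lag autocovariance sequence is read off its
#' covariance matrix (averaging along diagonals), Hann-tapered and Fourier
#' transformed; the peak frequency per state is reported. A resolution flag
#' is set when the window is short (`2L + 1 < 11` samples).
#'
#' @param model fitted `hmm_model`.
#' @param fs sampling rate of the modelled signal (Hz).
#' @param freqs frequency grid in Hz.
#' @return A list with `freq`, `power` (states x frequencies matrix),
#'   `peak_freq` per state, and `low_resolution` flag.
#' @export
state_spectra <- function(model, fs = 100, freqs = seq(1, 50, by = 0.5)) {
  d <- 2 * model$L + 1
  lags <- 0:(d - 1)
  taper <- 0.5 + 0.5 * cos(pi * lags / d) # Hann-type lag window
  pow <- matrix(0, model$K, length(freqs))
  for (k in seq_len(model$K)) {
    S <- model$Sigma[, , k]
    acov <- vapply(lags, function(tau) mean(S[row(S) == col(S) - tau]), 0)
    for (i in seq_along(freqs)) {
      pow[k, i] <- acov[1] + 2 * sum(taper[-1] * acov[-1] * cos(2 * pi * freqs[i] * lags[-1] / fs))
    }
  }
  pow[pow < 0] <- 0
  list(freq = freqs, power = pow,
       peak_freq = freqs[apply(pow, 1, which.max)],
       low_resolution = d < 11)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("TDE-HMM: K = %d states, L = %d lags (window %d samples)\n",
              x$K, x$L, 2 * x$L + 1))
  cat(sprintf("  loglik %.1f after %d EM iterations (%s)\n", x$loglik,
              length(x$loglik_trace) - 1,
              if (x$converged) "converged" else "max_iter reached"))
  if (length(x$degenerate_states))
    cat("  degenerate states (occupancy < 10 samples):",
        paste(x$degenerate_states, collapse = ", "), "\n")
  invisible(x)
}

#' Default desk-scale model grid
#'
#' Configurable list of (K, L) pairs; the default desk grid spans
#' K in {6, 8, 10} states by L in {7, 11} lags (6 models).
#'
#' @return data.frame with columns `K` and `L`.
#' @export
default_model_grid <- function() {
  expand.grid(K = c(6L, 8L, 10L), L = c(7L, 11L))
}
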