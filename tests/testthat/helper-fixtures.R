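# Shared fixtures: small planted signals and brute-force HMM oracles.

# Alternating 6 Hz / 20 Hz epochs (SNR ~ 3 against unit white noise),
# z-normalized; returns the signal and per-sample regime labels (1 = 6 Hz).
two_regime_signal <- function(n_total = 6000, fs = 100, amp = 3, seed = 1) {
  set.seed(seed)
  x <- c()
  lab <- c()
  regime <- 1
  while (length(x) < n_total) {
    n <- round(runif(1, 100, 200))
    f <- if (regime == 1) 6 else 20
    t <- seq(0, by = 1 / fs, length.out = n)
    x <- c(x, amp * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) + rnorm(n))
    lab <- c(lab, rep(regime, n))
    regime <- 3 - regime
  }
  list(x = (x - mean(x)) / sd(x), labels = lab, fs = fs)
}

# Exact HMM posteriors by enumeration over all K^T paths.
brute_force_posteriors <- function(A, pi, log_dens) {
  T_ <- nrow(log_dens)
  K <- ncol(log_dens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(pi[s[1]]) + log_dens[1, s[1]]
    if (T_ > 1) for (t in 2:T_) lp <- lp + log(A[s[t - 1], s[t]]) + log_dens[t, s[t]]
    lp
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  gamma <- sapply(seq_len(K), function(k)
    sapply(seq_len(T_), function(t) sum(w[paths[, t] == k])))
  list(gamma = matrix(gamma, T_, K),
       loglik = log(sum(exp(logp - max(logp)))) + max(logp),
       best_path = as.integer(paths[which.max(logp), ]))
}

# Random stochastic matrix / distribution for oracle grids.
random_stochastic <- function(K) {
  A <- matrix(runif(K * K) + 0.1, K, K)
  A / rowSums(A)
}

# A session object wrapping a plain signal matrix.
make_session <- function(signal, fs = 100, hemisphere = "h01", condition = "OFF") {
  structure(list(signal = as.matrix(signal), fs = fs,
                 hemisphere_id = hemisphere, condition = condition,
                 channel_labels = as.character(seq_len(ncol(as.matrix(signal))))),
            class = "session")
}

# Tiny cohort spec for pipeline tests.
tiny_cohort_spec <- function(seed = 1, n = 6, dur = 25) {
  cohort_spec(n_hemispheres = n, duration_s = dur, seed = seed)
}
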