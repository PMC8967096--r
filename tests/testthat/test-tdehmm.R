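test_that("time-delay embedding matches its definition", {
  e <- embed_delay(c(1, 2, 3, 4, 5), 1)
  expect_equal(e$Y, rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(e$time_index, 1:3)

  e2 <- embed_delay(c(1, 2, 3, 4, 5), 2)
  expect_equal(e2$Y, matrix(1:5, 1))

  expect_error(embed_delay(c(1, 2, 3), 2), "shorter")

  # no cross-boundary rows: two segments each lose 2L edge samples
  x <- rnorm(200)
  b <- data.frame(start = c(0, 120), end = c(120, 200))
  e3 <- embed_delay(x, 5, b)
  expect_equal(nrow(e3$Y), (120 - 10) + (80 - 10))
  expect_equal(e3$seg_start, c(0, 110))
  expect_equal(e3$seg_end, c(110, 180))
})

test_that("embedded white noise has near-diagonal covariance", {
  set.seed(4)
  e <- embed_delay(rnorm(1e5), 3)
  cm <- cor(e$Y)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
})

test_that("forward-backward matches brute-force path enumeration", {
  set.seed(10)
  for (K in 1:3) {
    for (T_ in c(2, 5, 8)) {
      A <- random_stochastic(K)
      pi <- as.numeric(random_stochastic(K)[1, ])
      logd <- matrix(log(runif(T_ * K, 0.05, 1)), T_, K)
      fb <- forward_backward(A, pi, logd)
      bf <- brute_force_posteriors(A, pi, logd)
      expect_lt(max(abs(fb$gamma - bf$gamma)), 1e-10)
      expect_lt(abs(fb$loglik - bf$loglik), 1e-10)
      expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-8)
      # Viterbi against the argmax path of the enumeration
      expect_equal(viterbi_decode(A, pi, logd), bf$best_path)
    }
  }
})

test_that("forward-backward limit cases behave", {
  # K = 1: posteriors all one, loglik = sum of the densities
  logd <- matrix(log(runif(6, 0.1, 1)), 6, 1)
  fb <- forward_backward(matrix(1, 1, 1), 1, logd)
  expect_equal(as.numeric(fb$gamma), rep(1, 6))
  expect_equal(fb$loglik, sum(logd))
  expect_equal(viterbi_decode(matrix(1, 1, 1), 1, logd), rep(1L, 6))

  # absorbing chain locked to state 1
  A <- diag(2)
  logd2 <- matrix(log(runif(8, 0.1, 1)), 4, 2)
  fb2 <- forward_backward(A, c(1, 0), logd2)
  expect_equal(fb2$gamma[, 1], rep(1, 4))

  # uniform densities and transitions: Viterbi follows the prior
  logd3 <- matrix(0, 5, 2)
  expect_equal(viterbi_decode(matrix(0.5, 2, 2), c(0.3, 0.7), logd3), rep(2L, 5))

  expect_error(forward_backward(matrix(c(1, 1, 0, 1), 2), c(.5, .5), logd2),
               "row-stochastic")
})

test_that("EM log-likelihood is monotone and fits recover planted regimes", {
  sig <- two_regime_signal(seed = 3)
  tde <- embed_delay(sig$x, 7)
  m <- fit_hmm(tde, hmm_config(K = 2, L = 7, max_iter = 25, n_restarts = 2, seed = 1))

  expect_true(all(diff(m$loglik_trace) >= -1e-8 * abs(m$loglik_trace[-1])))
  expect_lt(max(abs(rowSums(m$gamma) - 1)), 1e-8)
  expect_lt(max(abs(rowSums(m$A) - 1)), 1e-10)
  expect_equal(sum(m$pi), 1, tolerance = 1e-10)

  lab <- sig$labels[tde$time_index + 1]
  acc <- max(mean(m$path == lab), mean((3 - m$path) == lab))
  expect_gte(acc, 0.9)

  # state spectra peak at the planted frequencies (in some state order)
  peaks <- sort(state_spectra(m)$peak_freq)
  expect_lt(abs(peaks[1] - 6), 2)
  expect_gte(peaks[2], 13)
  expect_lte(peaks[2], 21)
})

test_that("single-regime data yield one dominant state or twin covariances", {
  # iid draws from one Gaussian: either one state takes over or the two
  # states become interchangeable. (Delay-embedded noise is deliberately
  # not used here: overlapping windows make rows dependent, and the HMM
  # can legitimately latch onto local-variance clustering.)
  set.seed(5)
  Y <- matrix(rnorm(8000 * 3), ncol = 3)
  m <- fit_hmm(Y, hmm_config(K = 2, L = 1, max_iter = 30, n_restarts = 1, seed = 2))
  fo <- c(mean(m$path == 1), mean(m$path == 2))
  frob <- norm(m$Sigma[, , 1] - m$Sigma[, , 2], "F") / norm(m$Sigma[, , 1], "F")
  expect_true(max(fo) >= 0.95 || frob < 0.05)
})

test_that("relabeling states leaves the likelihood unchanged", {
  sig <- two_regime_signal(n_total = 3000, seed = 6)
  tde <- embed_delay(sig$x, 3)
  m <- fit_hmm(tde, hmm_config(K = 3, L = 3, max_iter = 10, n_restarts = 1, seed = 1))
  perm <- c(3, 1, 2)
  es <- hmm_estep_cpp(tde$Y, tde$seg_start, tde$seg_end,
                      m$A[perm, perm], m$pi[perm], m$Sigma[, , perm])
  expect_equal(es$loglik, m$loglik, tolerance = 1e-8)
})

test_that("decoding maps a fitted model onto new segments", {
  sig <- two_regime_signal(seed = 8)
  tde <- embed_delay(sig$x, 5)
  m <- fit_hmm(tde, hmm_config(K = 2, L = 5, max_iter = 15, n_restarts = 1, seed = 4))
  # decode a two-segment version of the same signal
  b <- data.frame(start = c(0, 3000), end = c(3000, length(sig$x)))
  tde2 <- embed_delay(sig$x, 5, b)
  m2 <- decode_states(m, tde2)
  expect_equal(length(m2$path), nrow(tde2$Y))
  lab <- sig$labels[tde2$time_index + 1]
  acc <- max(mean(m2$path == lab), mean((3 - m2$path) == lab))
  expect_gte(acc, 0.9)
  expect_error(decode_states(m, embed_delay(sig$x, 3)), "dimension mismatch")
})

test_that("state spectra respond to the covariance as documented", {
  sig <- two_regime_signal(seed = 12)
  tde <- embed_delay(sig$x, 7)
  m <- fit_hmm(tde, hmm_config(K = 2, L = 7, max_iter = 15, n_restarts = 1, seed = 2))

  # identity covariance: flat spectrum
  m_id <- m
  m_id$Sigma[, , 1] <- diag(15)
  ssf <- state_spectra(m_id)
  expect_lt(max(ssf$power[1, ]) / min(ssf$power[1, ]), 1.1)

  # identical covariances: identical spectra
  m_id$Sigma[, , 2] <- m_id$Sigma[, , 1]
  ss2 <- state_spectra(m_id)
  expect_equal(ss2$power[1, ], ss2$power[2, ])

  # short windows flag their limited resolution
  e <- embed_delay(sig$x, 2)
  m3 <- fit_hmm(e, hmm_config(K = 2, L = 2, max_iter = 5, n_restarts = 1, seed = 1))
  expect_true(state_spectra(m3)$low_resolution)
  expect_false(state_spectra(m)$low_resolution)
})

test_that("viterbi pathing is available through the configuration", {
  sig <- two_regime_signal(n_total = 3000, seed = 9)
  tde <- embed_delay(sig$x, 3)
  m <- fit_hmm(tde, hmm_config(K = 2, L = 3, max_iter = 10, n_restarts = 1,
                               seed = 1, pathing = "viterbi"))
  vp <- viterbi_path(m, tde)
  expect_equal(m$path, vp)
  lab <- sig$labels[tde$time_index + 1]
  expect_gte(max(mean(vp == lab), mean((3 - vp) == lab)), 0.85)
})
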