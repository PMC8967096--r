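test_that("burst trains follow the Poisson/gamma event model", {
  spec <- burst_process_spec("low_beta", rate = 1, mean_duration = 0.2)

  set.seed(1)
  zero <- burst_process_spec("low_beta", rate = 0, mean_duration = 0.2)
  expect_equal(nrow(simulate_burst_train(zero, 100, 100)), 0)

  # event count within the central 99% Poisson mass for mean rate*duration;
  # durations kept very short so post-merge counts equal event counts
  set.seed(2)
  short <- burst_process_spec("low_beta", rate = 1, mean_duration = 0.02)
  counts <- replicate(5, nrow(simulate_burst_train(short, 200, 100)))
  expect_true(all(counts >= qpois(0.005, 200) & counts <= qpois(0.995, 200)))

  # heavy merging: total covered time cannot exceed the session
  set.seed(3)
  heavy <- burst_process_spec("theta", rate = 1, mean_duration = 10)
  iv <- simulate_burst_train(heavy, 20, 100)
  expect_lte(sum(iv[, 2] - iv[, 1]), 20 * 100)
  expect_true(all(iv[, 1] >= 0 & iv[, 2] <= 2000))
  # merged intervals are disjoint and sorted
  if (nrow(iv) > 1) expect_true(all(iv[-1, 1] > iv[-nrow(iv), 2]))

  expect_error(burst_process_spec("low_beta", rate = -1, mean_duration = 0.2))
  expect_error(burst_process_spec("low_beta", rate = Inf, mean_duration = 0.2))
})

test_that("planted burst rate is recovered within 3 Poisson SDs", {
  spec <- burst_process_spec("alpha", rate = 0.4, mean_duration = 0.15)
  set.seed(7)
  dur <- 500
  iv <- simulate_burst_train(spec, dur, 100)
  lambda <- 0.4 * dur
  expect_lt(abs(nrow(iv) - lambda), 3 * sqrt(lambda))
})

test_that("raising the planted rate shortens the measured interval times", {
  # occurrence-rate / interval-time reciprocity across a 3-point rate sweep
  set.seed(19)
  gaps <- sapply(c(0.3, 0.6, 1.2), function(rate) {
    spec <- burst_process_spec("low_beta", rate = rate, mean_duration = 0.2)
    g <- replicate(4, {
      iv <- simulate_burst_train(spec, 300, 100)
      mean(iv[-1, 1] - iv[-nrow(iv), 2])
    })
    mean(g)
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("sessions place planted spectral content in the right band and channel", {
  spec <- cohort_spec(n_hemispheres = 2, duration_s = 30, seed = 42,
                      off_specs = list(low_beta = burst_process_spec(
                        "low_beta", rate = 1.5, mean_duration = 0.6, amplitude = 8,
                        amplitude_jitter = 0)),
                      on_specs = list(low_beta = burst_process_spec(
                        "low_beta", rate = 1.5, mean_duration = 0.6, amplitude = 8,
                        amplitude_jitter = 0)),
                      coupling = c(low_beta_rate = 1))
  s <- simulate_lfp_session(spec, "OFF", "h01")
  ps <- welch_psd(s$session$signal[, 2], spec$fs_raw, nfft = 512)
  sel <- ps$freq >= 2 & ps$freq <= 48
  peak <- ps$freq[sel][which.max(ps$power[sel])]
  expect_gte(peak, 13)
  expect_lte(peak, 21)
  # burst content concentrated on channel 2: its beta power dominates
  bp <- sapply(1:3, function(ch) band_power(s$session$signal[, ch], spec$fs_raw, 13, 21))
  expect_equal(which.max(bp), 2)
})

test_that("pure-noise sessions show no planted band structure", {
  spec <- cohort_spec(n_hemispheres = 2, duration_s = 60, seed = 5,
                      off_specs = list(theta = burst_process_spec("theta", 0, 0.3)),
                      on_specs = list(theta = burst_process_spec("theta", 0, 0.3)),
                      coupling = c(theta_rate = 0))
  s <- simulate_lfp_session(spec, "OFF", "h01")$session
  x <- (s$signal[, 2] - mean(s$signal[, 2])) / sd(s$signal[, 2])
  env <- band_envelopes(x, fs = spec$fs_raw)
  # no planted peaks: band envelope means all of the same order
  m <- colMeans(env)
  expect_lt(max(m) / min(m), 3)
})

test_that("simulation is deterministic given seed and arguments", {
  spec <- tiny_cohort_spec(seed = 11)
  a <- simulate_lfp_session(spec, "ON", "h02")
  b <- simulate_lfp_session(spec, "ON", "h02")
  expect_identical(a$session$signal, b$session$signal)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1$scores, co2$scores)
  expect_identical(co1$sessions[["h03"]]$OFF$signal, co2$sessions[["h03"]]$OFF$signal)
})

test_that("zero coupling with zero score noise gives identical OFF and ON scores", {
  spec <- cohort_spec(n_hemispheres = 4, duration_s = 10, seed = 3,
                      coupling = c(low_beta_fo = 0), score_noise_sd = 0)
  co <- simulate_cohort(spec)
  sc <- hemibody_scores(co$scores)
  off <- sc$scores[sc$scores$condition == "OFF", ]
  on <- sc$scores[sc$scores$condition == "ON", ]
  m <- match(off$hemisphere, on$hemisphere)
  expect_equal(off$total, on$total[m])
  expect_true(all(sc$pct_change$total[off$total > 0] == 0))
})

test_that("score coupling hits the calibrated explainable variance", {
  ev <- replicate(4, NA_real_)
  for (i in seq_along(ev)) {
    co <- simulate_cohort(cohort_spec(n_hemispheres = 64, duration_s = 20, seed = 100 + i))
    sc <- hemibody_scores(co$scores)
    comp <- co$truth$score_components
    cp <- comp$coupled_pct[comp$condition == "OFF"]
    ev[i] <- cor(sc$pct_change$total, cp)^2
  }
  expect_gt(mean(ev), 0.35)
  expect_lt(mean(ev), 0.65)
})

test_that("unknown coupling features are rejected", {
  expect_error(cohort_spec(coupling = c(delta_rate = 1)), "unknown")
  expect_error(cohort_spec(n_hemispheres = 1), "n_hemispheres")
  expect_error(cohort_spec(fs_raw = 100), "fs_raw")
})

test_that("cohorts round-trip through the on-disk interchange format", {
  co <- simulate_cohort(tiny_cohort_spec(seed = 9, n = 2, dur = 5))
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_equal(back$sessions[["h01"]]$OFF$signal, co$sessions[["h01"]]$OFF$signal,
               tolerance = 1e-6)
  expect_identical(back$sessions[["h02"]]$ON$condition, "ON")
  expect_equal(back$scores$item22, co$scores$item22)
})
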