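test_that("visits are maximal runs split at session boundaries", {
  v <- extract_visits(c(1, 1, 2, 2, 2, 1))
  expect_equal(v$state, c(1, 2, 1))
  expect_equal(v$start, c(0, 2, 5))
  expect_equal(v$end, c(2, 5, 6))

  # boundary split
  v2 <- extract_visits(c(1, 1, 1, 1), seg_start = c(0, 3), seg_end = c(3, 4))
  expect_equal(v2$start, c(0, 3))
  expect_equal(v2$end, c(3, 4))

  v3 <- extract_visits(rep(2, 10))
  expect_equal(nrow(v3), 1)
  expect_equal(v3$duration_s, 0.1)
})

test_that("dwell statistics match hand counts on the 6-sample toy", {
  v <- extract_visits(c(1, 1, 2, 2, 2, 1))
  sf <- summary_features(v, 6, K = 2)
  ps <- sf$per_state
  expect_equal(ps$fractional_occupancy, c(0.5, 0.5))
  expect_equal(ps$life_time, c(0.015, 0.030))
  expect_equal(ps$occurrence_rate[1], 2 / 0.06)
  expect_equal(ps$interval_time[1], 0.03)
  expect_true(is.na(ps$interval_time[2]))

  # accounting identity: FO x total duration = life_time x visit count
  for (k in 1:2) {
    visits_k <- sum(v$state == k)
    expect_equal(ps$fractional_occupancy[k] * 0.06,
                 ps$life_time[k] * visits_k)
  }

  one <- summary_features(extract_visits(rep(1, 50)), 50, K = 1)
  expect_equal(one$per_state$fractional_occupancy, 1)
  expect_equal(one$per_state$occurrence_rate, 1 / 0.5)
  expect_true(is.na(one$per_state$interval_time))

  expect_error(summary_features(v, 0, 2), "zero-length")
})

test_that("duration bins use half-open edges and normalize", {
  v <- data.frame(state = 1, duration_s = c(0.05, 0.15, 1.2))
  dbc <- duration_binned_counts(v, K = 1)
  expect_equal(as.numeric(dbc$counts), c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(as.numeric(dbc$relative), c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1) / 3)

  # exactly 0.1 s lands in the second bin; durations arrive as samples/100
  v2 <- data.frame(state = 1, duration_s = 10 / 100)
  expect_equal(as.numeric(duration_binned_counts(v2, 1)$counts)[2], 1)

  expect_equal(sum(dbc$relative), 1)
  # no visits: all-missing relative row
  empty <- duration_binned_counts(data.frame(state = integer(), duration_s = numeric()), 1)
  expect_true(all(is.na(empty$relative)))
})

test_that("band transition matrix counts consecutive visits", {
  visits <- data.frame(state = c(1, 2, 1, 2), segment = 1)
  bm <- data.frame(state = 1:2, band = c("theta", "low_beta"))
  tm <- band_transition_matrix(visits, bm)
  expect_equal(tm["theta", "low_beta"], 1)
  expect_equal(tm["low_beta", "theta"], 1)
  rs <- rowSums(tm)
  expect_true(all(abs(rs[!is.na(rs)] - 1) < 1e-12))

  # single visit: nothing to count
  tm1 <- band_transition_matrix(data.frame(state = 1, segment = 1), bm)
  expect_true(all(is.na(tm1)))

  # transitions never span segments
  visits2 <- data.frame(state = c(1, 2), segment = c(1, 2))
  tm2 <- band_transition_matrix(visits2, bm)
  expect_true(all(is.na(tm2)))
})

test_that("band collapse sums rates and occupancy-weights times", {
  ps <- data.frame(state = 1:3,
                   fractional_occupancy = c(0.1, 0.2, 0.3),
                   life_time = c(0.2, 0.4, 0.5),
                   interval_time = c(1, 2, 4),
                   occurrence_rate = c(0.5, 0.5, 0.6))
  bm <- data.frame(state = 1:3, band = c("low_beta", "low_beta", "theta"))
  blf <- band_level_features(ps, bm)
  lb <- blf[blf$band == "low_beta", ]
  expect_equal(lb$fractional_occupancy, 0.3)
  expect_equal(lb$occurrence_rate, 1.0)
  expect_equal(lb$life_time, (0.1 * 0.2 + 0.2 * 0.4) / 0.3)
  expect_equal(lb$interval_time, (0.1 * 1 + 0.2 * 2) / 0.3)
  # identity collapse: one state per band
  solo <- band_level_features(ps[3, ], data.frame(state = 3, band = "theta"))
  expect_equal(solo$life_time[solo$band == "theta"], 0.5)
  expect_true(is.na(solo$fractional_occupancy[solo$band == "alpha"]))
})

test_that("amplitude features are linear in the signal", {
  set.seed(6)
  x <- sin(2 * pi * 17 * seq(0, 20, by = 0.01)[-1])
  env1 <- band_envelopes(x, fs = 100)
  env2 <- band_envelopes(2 * x, fs = 100)
  a1 <- amplitude_features(env1)
  a2 <- amplitude_features(env2)
  expect_equal(a2, 2 * a1, tolerance = 1e-10)
  expect_gte(a1["low_beta"], 0.8)
  expect_lte(a1["low_beta"], 1.1)
  expect_equal(unname(amplitude_features(band_envelopes(rep(0, 500), fs = 100))),
               rep(0, 4))
})

test_that("feature tables keep per-session accounting identities", {
  co <- simulate_cohort(tiny_cohort_spec(seed = 13, n = 3, dur = 20))
  concat <- preprocess_cohort(co)
  tde <- embed_delay(concat, 3)
  m <- fit_hmm(tde, hmm_config(K = 3, L = 3, max_iter = 8, n_restarts = 1, seed = 2))
  ft <- feature_table(m, assign_bands(m, band_envelopes(concat)))

  # state FOs sum to 1 in every session
  for (h in unique(ft$hemisphere)) for (cond in c("OFF", "ON")) {
    fo <- ft$value[ft$hemisphere == h & ft$condition == cond &
                     ft$level == "state" & ft$feature == "fractional_occupancy"]
    expect_equal(sum(fo), 1, tolerance = 1e-9)
  }
  # delta rows equal ON - OFF
  key <- function(d) paste(d$hemisphere, d$level, d$unit, d$feature)
  off <- ft[ft$condition == "OFF", ]
  on <- ft[ft$condition == "ON", ]
  del <- ft[ft$condition == "delta", ]
  m1 <- match(key(del), key(off))
  m2 <- match(key(del), key(on))
  expect_equal(del$value, on$value[m2] - off$value[m1], tolerance = 1e-12)
})
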