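#' Canonical frequency bands
#'
#' The four sub-40 Hz bands used throughout (theta 4-7 Hz, alpha 8-12 Hz,
#' low beta 13-21 Hz, high beta 22-35 Hz), plus gamma (60-90 Hz) for the
#' secondary analysis. `center` is the carrier frequency used when planting
#' synthetic bursts.
#'
#' @param gamma include the gamma band row.
#' @return data.frame with columns `band`, `f_lo`, `f_hi`, `center`.
#' @export
default_bands <- function(gamma = FALSE) {
  b <- data.frame(
    band   = c("theta", "alpha", "low_beta", "high_beta"),
    f_lo   = c(4, 8, 13, 22),
    f_hi   = c(7, 12, 21, 35),
    center = c(5.5, 10, 17, 28),
    stringsAsFactors = FALSE
  )
  if (gamma) b <- rbind(b, data.frame(band = "gamma", f_lo = 60, f_hi = 90, center = 75))
  b
}

#' Burst process specification
#'
#' One band's transient-oscillation process: Poisson event onsets, gamma
#' distributed durations, Hann-tapered sinusoidal events at the band's center
#' frequency.
#'
#' @param band band name (one of `default_bands()$band`).
#' @param rate events per second (Poisson intensity).
#' @param mean_duration mean event duration in seconds.
#' @param duration_shape gamma-distribution shape for durations.
#' @param amplitude event amplitude in z-units (relative to unit background).
#' @param amplitude_jitter fractional uniform jitter on per-event amplitude.
#' @return An object of class `burst_process_spec`.
#' @export
burst_process_spec <- function(band, rate, mean_duration, duration_shape = 2,
                               amplitude = 2.5, amplitude_jitter = 0.2) {
  stopifnot_finite(c(rate, mean_duration, duration_shape, amplitude, amplitude_jitter),
                   "burst process parameters")
  if (rate < 0) stop("rate must be >= 0")
  if (mean_duration <= 0) stop("mean_duration must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  bands <- default_bands(gamma = TRUE)
  if (!band %in% bands$band) stop("unknown band: ", band)
  structure(list(band = band, rate = rate, mean_duration = mean_duration,
                 duration_shape = duration_shape, amplitude = amplitude,
                 amplitude_jitter = amplitude_jitter,
                 f_center = bands$center[bands$band == band]),
            class = "burst_process_spec")
}

default_burst_specs <- function(condition = c("OFF", "ON")) {
  condition <- match.arg(condition)
  # Condition-dependent burst statistics: low beta suppressed and briefer ON;
  # theta/alpha (and mildly high beta) enhanced ON.
  # amplitudes sit in the well-separated regime (envelope SNR ~ 3 against
  # the unit 1/f background), with low beta the most prominent transient
  if (condition == "OFF") {
    list(
      theta     = burst_process_spec("theta",     rate = 0.25, mean_duration = 0.45, amplitude = 3.0),
      alpha     = burst_process_spec("alpha",     rate = 0.25, mean_duration = 0.35, amplitude = 2.8),
      low_beta  = burst_process_spec("low_beta",  rate = 0.80, mean_duration = 0.35, amplitude = 3.2),
      high_beta = burst_process_spec("high_beta", rate = 0.30, mean_duration = 0.25, amplitude = 2.5)
    )
  } else {
    list(
      theta     = burst_process_spec("theta",     rate = 0.50, mean_duration = 0.55, amplitude = 3.0),
      alpha     = burst_process_spec("alpha",     rate = 0.40, mean_duration = 0.40, amplitude = 2.8),
      low_beta  = burst_process_spec("low_beta",  rate = 0.45, mean_duration = 0.25, amplitude = 3.2),
      high_beta = burst_process_spec("high_beta", rate = 0.40, mean_duration = 0.30, amplitude = 2.5)
    )
  }
}

default_coupling <- function() {
  # Weights linking true per-condition burst features to hemibody score.
  # Positive low-beta weights (more/longer low-beta bursting = worse motor
  # state), negative theta/alpha/high-beta weights (these states oppose it).
  # Occupancy and duration carry most of the weight: they are the burst
  # statistics an amplitude-referenced detector identifies well, whereas the
  # latent event rate is only weakly identified once events merge and ride
  # on 1/f background.
  c(low_beta_fo = 1.0, low_beta_mean_duration = 0.6, low_beta_rate = 0.3,
    theta_fo = -0.7, theta_rate = -0.2,
    alpha_fo = -0.5, high_beta_fo = -0.35)
}

#' Synthetic cohort specification
#'
#' Describes a cohort of hemispheres recorded OFF and ON medication: bursty
#' band-limited oscillations over 1/f background, with hemibody clinical
#' scores linearly coupled (plus noise) to the true burst features. Defaults
#' emulate the study conditions: 64 hemispheres, ~390 s sessions, low beta
#' suppressed ON, theta/alpha enhanced ON.
#'
#' Between-hemisphere heterogeneity (log-normal multipliers on rates,
#' durations and amplitudes) provides the across-cohort variance that the
#' score coupling transmits; the coupling weights are rescaled internally so
#' the coupled score component has standard deviation `signal_sd` points,
#' and the score noise is calibrated from `explainable_variance` (see
#' [simulate_cohort()]).
#'
#' @param n_hemispheres number of hemispheres (each with an OFF and ON session).
#' @param duration_s session duration in seconds.
#' @param fs_raw raw sampling rate in Hz (>= 200 so 2-48 Hz content is
#'   representable before resampling).
#' @param noise_exponent 1/f^a slope of the background.
#' @param noise_level background standard deviation in z-units.
#' @param off_specs,on_specs named lists of [burst_process_spec()] per band.
#' @param coupling named numeric vector of relative weights over
#'   `<band>_<stat>` features with stat in rate, mean_duration, fo.
#' @param explainable_variance fraction of score-change variance carried by
#'   the coupled component (noise calibrated to match); ignored when all
#'   coupling weights are zero.
#' @param signal_sd standard deviation (score points) of the coupled
#'   component of the OFF-ON score change.
#' @param score_noise_sd score noise SD used when coupling is all zero.
#' @param rate_log_sd,duration_log_sd,amplitude_log_sd between-hemisphere
#'   log-normal spread of burst rates, durations and amplitudes.
#' @param noise_exponent_sd spread of the 1/f exponent across recordings
#'   (drawn per hemisphere and condition: the aperiodic background is not
#'   stable across medication states).
#' @param seed integer root seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hemispheres = 64, duration_s = 390, fs_raw = 200,
                        noise_exponent = 1, noise_level = 1,
                        off_specs = default_burst_specs("OFF"),
                        on_specs = default_burst_specs("ON"),
                        coupling = default_coupling(),
                        explainable_variance = 0.5, signal_sd = 4,
                        score_noise_sd = 3,
                        rate_log_sd = 0.45, duration_log_sd = 0.3,
                        amplitude_log_sd = 0.2, noise_exponent_sd = 0.12,
                        seed = 1L) {
  if (n_hemispheres < 2) stop("n_hemispheres must be >= 2")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (fs_raw < 200) stop("fs_raw must be >= 200 Hz")
  known <- unlist(lapply(names(off_specs), function(b) paste0(b, c("_rate", "_mean_duration", "_fo"))))
  bad <- setdiff(names(coupling), known)
  if (length(bad)) stop("coupling references unknown features: ", paste(bad, collapse = ", "))
  structure(list(n_hemispheres = as.integer(n_hemispheres), duration_s = duration_s,
                 fs_raw = fs_raw, noise_exponent = noise_exponent,
                 noise_level = noise_level, off_specs = off_specs,
                 on_specs = on_specs, coupling = coupling,
                 explainable_variance = explainable_variance,
                 signal_sd = signal_sd, score_noise_sd = score_noise_sd,
                 rate_log_sd = rate_log_sd, duration_log_sd = duration_log_sd,
                 amplitude_log_sd = amplitude_log_sd,
                 noise_exponent_sd = noise_exponent_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic LFP cohort spec:", x$n_hemispheres, "hemispheres x 2 conditions,",
      x$duration_s, "s at", x$fs_raw, "Hz\n")
  cat("  coupled features:", paste(names(x$coupling), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a Poisson burst train
#'
#' Event onsets from a homogeneous Poisson process, i.i.d. gamma durations;
#' overlapping events are merged and intervals clipped to the session.
#'
#' @param spec a [burst_process_spec()].
#' @param duration_s session length in seconds.
#' @param fs sampling rate in Hz.
#' @return 2-column matrix of half-open sample intervals `[start, end)`
#'   (0-based), one row per merged event.
#' @export
simulate_burst_train <- function(spec, duration_s, fs) {
  stopifnot(inherits(spec, "burst_process_spec"), duration_s > 0)
  n_ev <- stats::rpois(1, spec$rate * duration_s)
  if (n_ev == 0) return(matrix(numeric(0), 0, 2))
  onset <- sort(stats::runif(n_ev, 0, duration_s))
  dur <- stats::rgamma(n_ev, shape = spec$duration_shape,
                       scale = spec$mean_duration / spec$duration_shape)
  m <- cbind(round(onset * fs), round((onset + dur) * fs))
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  clip_intervals(merge_intervals(m), round(duration_s * fs))
}

# 1/f^a Gaussian background, standardized to sd = level.
pink_noise <- function(n, exponent, level) {
  if (level == 0) return(numeric(n))
  nf <- ifelse(n %% 2 == 0, n, n + 1)
  f <- seq_len(nf / 2)
  amp <- f^(-exponent / 2)
  ph <- stats::runif(nf / 2, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(0, spec, Conj(rev(spec[-(nf / 2)])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  level * (x - mean(x)) / stats::sd(x)
}

# Add Hann-tapered sinusoidal events on given sample intervals.
add_burst_waveforms <- function(x, intervals, f_center, amplitude, jitter, fs) {
  for (i in seq_len(nrow(intervals))) {
    a <- intervals[i, 1]
    b <- intervals[i, 2]
    idx <- (a + 1):b            # 1-based sample indices
    amp <- amplitude * (1 + jitter * stats::runif(1, -1, 1))
    phase <- stats::runif(1, 0, 2 * pi)
    t <- (idx - 1) / fs
    x[idx] <- x[idx] + amp * hann_window(length(idx)) * sin(2 * pi * f_center * t + phase)
  }
  x
}

# Hemisphere-level multipliers for one (hemisphere, condition); deterministic
# given (seed, hemisphere_id, condition).
hemisphere_multipliers <- function(spec, hemisphere_id, condition) {
  set.seed(derive_seed(spec$seed, "hemi", hemisphere_id, condition))
  bands <- names(spec$off_specs)
  list(rate = stats::setNames(exp(stats::rnorm(length(bands), 0, spec$rate_log_sd)), bands),
       duration = stats::setNames(exp(stats::rnorm(length(bands), 0, spec$duration_log_sd)), bands),
       amplitude = stats::setNames(exp(stats::rnorm(length(bands), 0, spec$amplitude_log_sd)), bands),
       noise_exponent = spec$noise_exponent +
         stats::rnorm(1, 0, spec$noise_exponent_sd %||% 0))
}

#' Simulate one LFP session
#'
#' Three bipolar-like channels of 1/f background; the planted burst content
#' is concentrated on the designated channel (channel 2) so that contact-pair
#' selection is exercised downstream. Deterministic given
#' `(spec$seed, hemisphere_id, condition)`.
#'
#' @param spec a [cohort_spec()].
#' @param condition `"OFF"` or `"ON"`.
#' @param hemisphere_id hemisphere identifier (integer or string).
#' @param burst_channel channel carrying the burst content.
#' @return A list with `session` (a `session` object: `signal` samples x
#'   channels, `fs`, `hemisphere_id`, `condition`, `channel_labels`) and
#'   `truth` (per-band merged burst intervals and true feature values).
#' @export
simulate_lfp_session <- function(spec, condition, hemisphere_id, burst_channel = 2) {
  stopifnot(inherits(spec, "cohort_spec"), condition %in% c("OFF", "ON"))
  fs <- spec$fs_raw
  n <- round(spec$duration_s * fs)
  mult <- hemisphere_multipliers(spec, hemisphere_id, condition)
  set.seed(derive_seed(spec$seed, "session", hemisphere_id, condition))
  sig <- sapply(1:3, function(ch) pink_noise(n, mult$noise_exponent, spec$noise_level))
  specs <- if (condition == "OFF") spec$off_specs else spec$on_specs
  intervals <- list()
  truth_rows <- list()
  for (b in names(specs)) {
    bs <- specs[[b]]
    eff <- burst_process_spec(b, rate = bs$rate * mult$rate[b],
                              mean_duration = bs$mean_duration * mult$duration[b],
                              duration_shape = bs$duration_shape,
                              amplitude = bs$amplitude * mult$amplitude[b],
                              amplitude_jitter = bs$amplitude_jitter)
    iv <- simulate_burst_train(eff, spec$duration_s, fs)
    intervals[[b]] <- iv
    sig[, burst_channel] <- add_burst_waveforms(sig[, burst_channel], iv, eff$f_center,
                                                eff$amplitude, eff$amplitude_jitter, fs)
    truth_rows[[b]] <- data.frame(
      hemisphere = hemisphere_id, condition = condition, band = b,
      rate = nrow(iv) / spec$duration_s,
      mean_duration = if (nrow(iv)) mean(iv[, 2] - iv[, 1]) / fs else 0,
      fo = sum(iv[, 2] - iv[, 1]) / n,
      stringsAsFactors = FALSE)
  }
  session <- structure(list(signal = sig, fs = fs,
                            hemisphere_id = as.character(hemisphere_id),
                            condition = condition,
                            channel_labels = c("01", "12", "23")),
                       class = "session")
  list(session = session,
       truth = list(intervals = intervals, features = do.call(rbind, truth_rows)))
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("LFP session: hemisphere %s, %s, %d ch x %d samples @ %g Hz\n",
              x$hemisphere_id, x$condition, ncol(x$signal), nrow(x$signal), x$fs))
  invisible(x)
}

#' Simulate a full synthetic cohort
#'
#' Generates per-hemisphere OFF and ON sessions plus a clinical-scores table
#' whose hemibody scores are `baseline + sum(coupling * true features) +
#' noise`, truncated at zero and rounded to UPDRS-like integers. The coupling
#' weights are rescaled so the coupled component of the OFF-ON score change
#' has SD `signal_sd`, and the additive score noise is calibrated so the
#' coupled component carries `explainable_variance` of the score-change
#' variance.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `sessions` (list over hemispheres of `list(OFF, ON)`),
#'   `scores` (data.frame: hemisphere, condition, item20..item26),
#'   `truth` (true burst intervals, true features, true score components),
#'   and `manifest` (data.frame of hemisphere/condition in session order).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  hemis <- sprintf("h%02d", seq_len(spec$n_hemispheres))
  sessions <- list()
  truths <- list()
  for (h in hemis) {
    off <- simulate_lfp_session(spec, "OFF", h)
    on <- simulate_lfp_session(spec, "ON", h)
    sessions[[h]] <- list(OFF = off$session, ON = on$session)
    truths[[h]] <- rbind(off$truth$features, on$truth$features)
    attr(truths[[h]], "intervals") <- list(OFF = off$truth$intervals, ON = on$truth$intervals)
  }
  true_feat <- do.call(rbind, lapply(truths, function(t) { attr(t, "intervals") <- NULL; t }))
  rownames(true_feat) <- NULL

  # linear predictor per (hemisphere, condition) from the coupled true features
  predictor <- function(h, cond) {
    tf <- true_feat[true_feat$hemisphere == h & true_feat$condition == cond, ]
    val <- 0
    for (f in names(spec$coupling)) {
      parts <- regmatches(f, regexec("^(.*)_(rate|mean_duration|fo)$", f))[[1]]
      val <- val + spec$coupling[[f]] * tf[tf$band == parts[2], parts[3]]
    }
    val
  }
  pred <- sapply(hemis, function(h) c(OFF = predictor(h, "OFF"), ON = predictor(h, "ON")))
  delta <- pred["OFF", ] - pred["ON", ]
  has_coupling <- any(spec$coupling != 0)
  ev <- spec$explainable_variance

  # OFF-level coupling: OFF score = baseline + scaled predictor + noise,
  # with the scaled predictor's spread fixed at signal_sd score points.
  lambda_off <- if (has_coupling && stats::sd(pred["OFF", ]) > 0)
    spec$signal_sd / stats::sd(pred["OFF", ]) else 0
  noise_off <- if (has_coupling) spec$signal_sd * sqrt((1 - ev) / ev) else spec$score_noise_sd

  # Percent-change coupling: the ON score is built from the OFF score so
  # that the percent improvement carries the coupled component of the
  # ON-OFF true-feature delta directly (spread signal_pct_sd percent
  # points), with the noise budgeted so the coupled share of the percent
  # change is the target explainable variance. Tremor shares the coupling
  # at a weaker gain and adds its own noise; the leading factor absorbs
  # the bradykinesia-rigidity/tremor mix in the total score.
  signal_pct_sd <- 12
  lambda_pc <- if (has_coupling && stats::sd(delta) > 0) signal_pct_sd / stats::sd(delta) else 0
  noise_pc <- if (has_coupling) signal_pct_sd * sqrt((1 - ev) / ev) else signal_pct_sd

  # fully degenerate contract: no coupling and no score noise means the
  # medication conditions are exchangeable, so OFF and ON scores coincide
  degenerate <- !has_coupling && spec$score_noise_sd == 0

  set.seed(derive_seed(spec$seed, "scores"))
  center_off <- mean(pred["OFF", ])
  center_d <- mean(delta)
  rows <- list()
  truth_scores <- list()
  for (h in hemis) {
    base_br <- stats::rnorm(1, 18, 2.5) # bradykinesia-rigidity hemibody baseline
    base_tr <- stats::rnorm(1, 4, 1.2)  # tremor baseline
    sig_off <- lambda_off * (pred["OFF", h] - center_off)
    off_br <- max(1, round(base_br + sig_off + stats::rnorm(1, 0, noise_off)))
    off_tr <- max(0, round(base_tr + 0.3 * sig_off + stats::rnorm(1, 0, if (degenerate) 0 else 0.3 * noise_off + 0.6)))
    sig_pc <- lambda_pc * (delta[h] - center_d)
    pc_br <- if (degenerate) 0 else min(95, 55 + sig_pc + stats::rnorm(1, 0, noise_pc))
    pc_tr <- if (degenerate) 0 else min(95, 40 + 0.6 * sig_pc + stats::rnorm(1, 0, noise_pc))
    on_br <- max(0, round(off_br * (1 - pc_br / 100)))
    on_tr <- max(0, round(off_tr * (1 - pc_tr / 100)))
    for (cond in c("OFF", "ON")) {
      br <- if (cond == "OFF") off_br else on_br
      tr <- if (cond == "OFF") off_tr else on_tr
      items_br <- as.vector(stats::rmultinom(1, br, rep(1 / 5, 5)))
      items_tr <- as.vector(stats::rmultinom(1, tr, rep(1 / 2, 2)))
      rows[[paste(h, cond)]] <- data.frame(
        hemisphere = h, condition = cond,
        item20 = items_tr[1], item21 = items_tr[2],
        item22 = items_br[1], item23 = items_br[2], item24 = items_br[3],
        item25 = items_br[4], item26 = items_br[5], stringsAsFactors = FALSE)
      truth_scores[[paste(h, cond)]] <- data.frame(
        hemisphere = h, condition = cond, predictor = pred[cond, h],
        coupled_off = sig_off, coupled_pct = sig_pc, stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  manifest <- data.frame(hemisphere = rep(hemis, each = 2),
                         condition = rep(c("OFF", "ON"), length(hemis)),
                         stringsAsFactors = FALSE)
  list(sessions = sessions, scores = scores,
       truth = list(features = true_feat,
                    intervals = lapply(truths, attr, "intervals"),
                    score_components = do.call(rbind, truth_scores),
                    lambda_off = lambda_off, lambda_pct = lambda_pc,
                    noise_off_sd = noise_off, noise_pct_sd = noise_pc),
       manifest = manifest, spec = spec)
}

#' Write a cohort to disk in the external-interface formats
#'
#' One whitespace-delimited numeric text file per session (samples x
#' channels) with a JSON sidecar (`fs_hz`, `hemisphere_id`, `condition`,
#' `channel_labels`), a cohort manifest CSV and a clinical-scores CSV.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame with file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (h in names(cohort$sessions)) {
    for (cond in c("OFF", "ON")) {
      s <- cohort$sessions[[h]][[cond]]
      sig_path <- file.path(dir, sprintf("%s_%s.txt", h, cond))
      side_path <- file.path(dir, sprintf("%s_%s.json", h, cond))
      utils::write.table(s$signal, sig_path, row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(list(fs_hz = s$fs, hemisphere_id = s$hemisphere_id,
                                condition = s$condition,
                                channel_labels = s$channel_labels),
                           side_path, auto_unbox = TRUE)
      rows[[paste(h, cond)]] <- data.frame(hemisphere_id = h, condition = cond,
                                           signal_path = sig_path,
                                           sidecar_path = side_path,
                                           stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and `scores.csv`.
#' @return A list with `sessions` and `scores` in the same shape as
#'   [simulate_cohort()] (without ground truth).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  scores <- utils::read.csv(file.path(dir, "scores.csv"), stringsAsFactors = FALSE)
  sessions <- list()
  for (i in seq_len(nrow(manifest))) {
    side <- jsonlite::read_json(manifest$sidecar_path[i], simplifyVector = TRUE)
    sig <- as.matrix(utils::read.table(manifest$signal_path[i]))
    dimnames(sig) <- NULL
    s <- structure(list(signal = sig, fs = side$fs_hz,
                        hemisphere_id = as.character(side$hemisphere_id),
                        condition = side$condition,
                        channel_labels = side$channel_labels),
                   class = "session")
    sessions[[side$hemisphere_id]][[side$condition]] <- s
  }
  list(sessions = sessions, scores = scores,
       manifest = manifest[, c("hemisphere_id", "condition")])
}
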