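#' Extract state visits from a hard path
#'
#' Maximal runs of constant state, split at session boundaries; no minimum
#' duration is applied.
#'
#' @param path integer state path (aligned to the embedded timeline).
#' @param seg_start,seg_end 0-based half-open row ranges, one per session.
#' @param boundaries optional session table (hemisphere, condition) aligned
#'   with the segments.
#' @param fs sampling rate (Hz) for durations.
#' @return data.frame of visits: `state`, `start`, `end` (0-based half-open
#'   rows), `duration_s`, `segment`, and session tags when available.
#' @export
extract_visits <- function(path, seg_start = 0, seg_end = length(path),
                           boundaries = NULL, fs = 100) {
  out <- list()
  for (s in seq_along(seg_start)) {
    idx <- (seg_start[s] + 1):seg_end[s]
    r <- rle(path[idx])
    ends <- seg_start[s] + cumsum(r$lengths)
    starts <- c(seg_start[s], head(ends, -1))
    v <- data.frame(state = r$values, start = starts, end = ends,
                    duration_s = r$lengths / fs, segment = s)
    if (!is.null(boundaries)) {
      v$hemisphere <- boundaries$hemisphere[s]
      v$condition <- boundaries$condition[s]
    }
    out[[s]] <- v
  }
  do.call(rbind, out)
}

#' Extract visits from a fitted model
#'
#' @param model fitted (or decoded) `hmm_model`.
#' @return Visits data.frame as from [extract_visits()], with session tags.
#' @export
model_visits <- function(model) {
  extract_visits(model$path, model$seg_start, model$seg_end,
                 boundaries = if (!is.null(model$boundaries$hemisphere)) model$boundaries else NULL)
}

#' Per-state dwell-statistics for one session
#'
#' Fractional occupancy (occupied samples / total), life time (mean visit
#' duration, s), interval time (mean gap between consecutive same-state
#' visits, s; missing with fewer than two visits), occurrence rate
#' (visits/s), and the session-level switching rate (state changes/s).
#'
#' @param visits visits of one session (from [extract_visits()]).
#' @param n_samples session length in samples (embedded timeline).
#' @param K number of states.
#' @param fs sampling rate in Hz.
#' @return A list with `per_state` (data.frame state, fractional_occupancy,
#'   life_time, interval_time, occurrence_rate) and `switching_rate`.
#' @export
summary_features <- function(visits, n_samples, K, fs = 100) {
  if (n_samples <= 0) stop("zero-length session")
  dur_total <- n_samples / fs
  per_state <- data.frame(state = seq_len(K), fractional_occupancy = 0,
                          life_time = NA_real_, interval_time = NA_real_,
                          occurrence_rate = 0)
  for (k in seq_len(K)) {
    v <- visits[visits$state == k, , drop = FALSE]
    if (nrow(v) == 0) next
    per_state$fractional_occupancy[k] <- sum(v$end - v$start) / n_samples
    per_state$life_time[k] <- mean(v$duration_s)
    per_state$occurrence_rate[k] <- nrow(v) / dur_total
    if (nrow(v) >= 2) {
      gaps <- v$start[-1] - v$end[-nrow(v)]
      per_state$interval_time[k] <- mean(gaps) / fs
    }
  }
  list(per_state = per_state,
       switching_rate = (nrow(visits) - 1) / dur_total)
}

# (0:9)/10 rather than seq(..., by = 0.1): durations arrive as k/100, which
# rounds to the same doubles as k/10 at the bin edges, so the half-open
# boundary rule is exact.
duration_bin_edges <- function() c((0:9) / 10, Inf)

duration_bin_labels <- function() {
  e <- duration_bin_edges()
  c("lt0.1", paste0(sprintf("%.1f", e[2:(length(e) - 2)]), "-",
                    sprintf("%.1f", e[3:(length(e) - 1)])), "gt0.9")
}

#' Duration-binned visit counts
#'
#' Counts per state over the bins <0.1, 0.1-0.2, ..., 0.8-0.9, >0.9 s
#' (half-open `[lo, hi)`, final bin open-ended) and relative counts
#' (bin count / total visits of the state; all-missing when no visits).
#'
#' @param visits visits data.frame.
#' @param K number of states.
#' @return A list with `counts` and `relative` (K x 10 matrices).
#' @export
duration_binned_counts <- function(visits, K) {
  edges <- duration_bin_edges()
  nb <- length(edges) - 1
  counts <- matrix(0, K, nb, dimnames = list(NULL, duration_bin_labels()))
  for (k in seq_len(K)) {
    d <- visits$duration_s[visits$state == k]
    if (length(d))
      counts[k, ] <- tabulate(findInterval(d, edges, left.open = FALSE), nbins = nb)
  }
  tot <- rowSums(counts)
  relative <- counts / ifelse(tot > 0, tot, NA)
  list(counts = counts, relative = relative)
}

band_levels <- function() c("theta", "alpha", "low_beta", "high_beta", "background")

#' Empirical band-to-band transition matrix
#'
#' Transition probabilities between consecutive visits mapped to band labels:
#' `P(next visit band = j | current band = i)`. Within-band (i to i) entries
#' count only switches between different states of a multi-state band, since
#' consecutive visits of the hard path always differ in state. Transitions
#' never span session boundaries; bands with no outgoing transitions get a
#' missing row.
#'
#' @param visits visits data.frame with a `segment` column.
#' @param band_map a `band_map` (state -> band).
#' @return 5 x 5 row-stochastic matrix over theta, alpha, low beta, high
#'   beta, background (rows with no transitions are `NA`).
#' @export
band_transition_matrix <- function(visits, band_map) {
  lv <- band_levels()
  vb <- band_map$band[visits$state]
  n <- length(vb)
  if (n < 2) return(matrix(NA_real_, 5, 5, dimnames = list(lv, lv)))
  keep <- visits$segment[-n] == visits$segment[-1]
  counts <- table(factor(vb[-n][keep], levels = lv),
                  factor(vb[-1][keep], levels = lv))
  counts <- matrix(as.numeric(counts), 5, 5, dimnames = list(lv, lv))
  rs <- rowSums(counts)
  counts / ifelse(rs > 0, rs, NA)
}

#' Collapse state-level features to band level
#'
#' Occurrence rates and duration-binned counts are summed over a band's
#' member states; fractional occupancy is summed; life time and interval
#' time are occupancy-weighted means. Bands with no member state are
#' missing.
#'
#' @param per_state per-state feature data.frame from [summary_features()].
#' @param band_map a `band_map`.
#' @return data.frame keyed by band with the collapsed features.
#' @export
band_level_features <- function(per_state, band_map) {
  lv <- band_levels()
  out <- data.frame(band = lv, fractional_occupancy = NA_real_,
                    life_time = NA_real_, interval_time = NA_real_,
                    occurrence_rate = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(lv)) {
    states <- band_map$state[band_map$band == lv[i]]
    if (!length(states)) next
    ps <- per_state[per_state$state %in% states, , drop = FALSE]
    w <- ps$fractional_occupancy
    out$fractional_occupancy[i] <- sum(w)
    out$occurrence_rate[i] <- sum(ps$occurrence_rate)
    wmean <- function(v) {
      ok <- !is.na(v) & w > 0
      if (!any(ok)) return(NA_real_)
      sum(v[ok] * w[ok]) / sum(w[ok])
    }
    out$life_time[i] <- wmean(ps$life_time)
    out$interval_time[i] <- wmean(ps$interval_time)
  }
  out
}

#' Mean band-envelope amplitude features
#'
#' Mean Hilbert envelope per band for one session; the amplitude features
#' used in the secondary (amplitude-augmented) regressions.
#'
#' @param envelopes envelope matrix (samples x bands) for one session.
#' @return Named numeric vector of per-band means.
#' @export
amplitude_features <- function(envelopes) {
  colMeans(envelopes)
}

#' Tidy per-session feature table for a fitted model
#'
#' Computes state- and band-level features for every session of a decoded
#' model, in the tidy layout `(hemisphere, condition, level, unit, feature,
#' value)`, and appends ON-OFF delta rows per hemisphere.
#'
#' @param model decoded `hmm_model` covering the cohort.
#' @param band_map a `band_map` for the model.
#' @param envelopes optional envelope matrix on the signal timeline to add
#'   amplitude features.
#' @return data.frame with columns hemisphere, condition (`OFF`, `ON` or
#'   `delta`), level (`state`, `band`, `session`), unit, feature, value.
#' @export
feature_table <- function(model, band_map, envelopes = NULL) {
  visits <- model_visits(model)
  bnd <- model$boundaries
  K <- model$K
  dwell <- c("fractional_occupancy", "life_time", "interval_time", "occurrence_rate")
  # fixed per-session layout, assembled once as vectors
  lev0 <- c(rep("state", 4 * K), "session", rep("band", 4 * 5),
            rep("state", 10 * K))
  unit0 <- c(rep(as.character(1:K), 4), "session", rep(band_levels(), 4),
             rep(as.character(1:K), 10))
  feat0 <- c(rep(dwell, each = K), "switching_rate", rep(dwell, each = 5),
             rep(paste0("relvisits_", duration_bin_labels()), each = K))
  if (!is.null(envelopes)) {
    lev0 <- c(lev0, rep("band", 4))
    unit0 <- c(unit0, colnames(envelopes))
    feat0 <- c(feat0, rep("amplitude", 4))
  }
  nS <- length(model$seg_start)
  vals <- matrix(NA_real_, length(lev0), nS)
  for (s in seq_len(nS)) {
    v <- visits[visits$segment == s, , drop = FALSE]
    n <- model$seg_end[s] - model$seg_start[s]
    sf <- summary_features(v, n, K)
    dbc <- duration_binned_counts(v, K)
    blf <- band_level_features(sf$per_state, band_map)
    st <- sf$per_state
    vv <- c(st$fractional_occupancy, st$life_time, st$interval_time,
            st$occurrence_rate, sf$switching_rate,
            blf$fractional_occupancy, blf$life_time, blf$interval_time,
            blf$occurrence_rate, as.numeric(dbc$relative))
    if (!is.null(envelopes)) {
      idx <- model$time_index[(model$seg_start[s] + 1):model$seg_end[s]] + 1
      vv <- c(vv, as.numeric(amplitude_features(envelopes[idx, , drop = FALSE])))
    }
    vals[, s] <- vv
  }
  tab <- data.frame(
    hemisphere = rep(bnd$hemisphere, each = length(lev0)),
    condition = rep(bnd$condition, each = length(lev0)),
    level = rep(lev0, nS), unit = rep(unit0, nS), feature = rep(feat0, nS),
    value = as.numeric(vals), stringsAsFactors = FALSE)
  rbind(tab, delta_rows(tab))
}

# ON - OFF delta rows per (hemisphere, level, unit, feature).
delta_rows <- function(tab) {
  off <- tab[tab$condition == "OFF", ]
  on <- tab[tab$condition == "ON", ]
  key <- function(d) paste(d$hemisphere, d$level, d$unit, d$feature, sep = "\r")
  m <- match(key(off), key(on))
  d <- off
  d$condition <- "delta"
  d$value <- on$value[m] - off$value
  d
}
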