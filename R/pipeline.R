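#' Analysis configuration
#'
#' Bundles the cohort (a [cohort_spec()] to simulate, or an already-simulated
#' / loaded cohort), the TDE-HMM model grid, the threshold percentile grid,
#' prediction modes and targets, and runtime knobs. All randomness flows
#' from `seed` via named substreams.
#'
#' @param cohort a `cohort_spec` or a cohort list.
#' @param model_grid data.frame of (K, L) pairs.
#' @param percentiles threshold percentile levels.
#' @param modes prediction design modes (`"delta"`, `"off"`).
#' @param targets score components to predict (`"total"`, `"bradyrigid"`,
#'   `"tremor"`).
#' @param fit_hemispheres number of hemispheres whose sessions are used for
#'   EM fitting (the full cohort is always decoded); `NULL` fits on all.
#' @param max_iter,tol,n_restarts EM settings per model.
#' @param do_threshold run the percentile-thresholding comparator arm.
#' @param do_stats run the permutation/FDR delta tests and the bivariate
#'   correlation grid.
#' @param do_subsets run the low-beta-only / non-low-beta feature-subset
#'   regressions.
#' @param amplitude_features add per-band mean-envelope amplitude features
#'   to the regression designs.
#' @param include_duration_bins include the duration-binned relative
#'   visit/burst counts as regressors (both arms). They are always computed
#'   and reported; as regressors at desk-scale cohort sizes they are mostly
#'   empty, collinear columns, so the default design uses the dwell
#'   features and switching rate only.
#' @param n_perm permutations for the stats arm.
#' @param seed root seed.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cohort = cohort_spec(),
                            model_grid = default_model_grid(),
                            percentiles = percentile_grid(),
                            modes = "delta", targets = "total",
                            fit_hemispheres = NULL,
                            max_iter = 20, tol = 5e-4, n_restarts = 4,
                            do_threshold = TRUE, do_stats = TRUE,
                            do_subsets = TRUE, amplitude_features = FALSE,
                            include_duration_bins = FALSE,
                            n_perm = 2000, seed = 1L) {
  structure(list(cohort = cohort, model_grid = model_grid,
                 percentiles = percentiles, modes = modes, targets = targets,
                 fit_hemispheres = fit_hemispheres, max_iter = max_iter,
                 tol = tol, n_restarts = n_restarts,
                 do_threshold = do_threshold, do_stats = do_stats,
                 do_subsets = do_subsets, amplitude_features = amplitude_features,
                 include_duration_bins = include_duration_bins,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Desk-scale study configuration
#'
#' The default end-to-end configuration used by the examples and the
#' reproduction script: the full 64-hemisphere cohort with 40 s sessions,
#' the 6-model (K, L) grid and the 23-percentile threshold grid, EM fitted
#' on a 10-hemisphere subset of sessions and decoded on the whole cohort.
#' Session length and the EM subset keep a complete grid run within minutes
#' on one core; the vignette discusses this scaling.
#'
#' @param seed root seed.
#' @param n_hemispheres,duration_s cohort size overrides.
#' @param ... further arguments to [analysis_config()].
#' @return An `analysis_config`.
#' @export
desk_config <- function(seed = 1L, n_hemispheres = 64, duration_s = 40, ...) {
  analysis_config(
    cohort = cohort_spec(n_hemispheres = n_hemispheres, duration_s = duration_s,
                         seed = derive_seed(seed, "cohort")),
    fit_hemispheres = 10, seed = seed, ...)
}

# Tidy rows for band-to-band transition probabilities, per session.
transition_feature_rows <- function(model, band_map) {
  visits <- model_visits(model)
  bnd <- model$boundaries
  rows <- list()
  for (s in seq_along(model$seg_start)) {
    tm <- band_transition_matrix(visits[visits$segment == s, , drop = FALSE], band_map)
    rows[[s]] <- data.frame(
      hemisphere = bnd$hemisphere[s], condition = bnd$condition[s],
      level = "transition",
      unit = paste0(rep(rownames(tm), 5), ">", rep(colnames(tm), each = 5)),
      feature = "trans_prob", value = as.numeric(tm), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rbind(tab, delta_rows(tab))
}

# Split a concatenated envelope matrix back into per-session matrices.
split_envelopes <- function(envelopes, boundaries) {
  out <- list()
  for (s in seq_len(nrow(boundaries))) {
    idx <- (boundaries$start[s] + 1):boundaries$end[s]
    out[[paste(boundaries$hemisphere[s], boundaries$condition[s])]] <-
      envelopes[idx, , drop = FALSE]
  }
  out
}

# Evenly-spaced hemisphere subset whose sessions are used for EM fitting.
fit_segment_subset <- function(tde, boundaries, n_fit) {
  hemis <- unique(boundaries$hemisphere)
  if (is.null(n_fit) || n_fit >= length(hemis)) return(tde)
  pick <- hemis[unique(round(seq(1, length(hemis), length.out = n_fit)))]
  segs <- which(boundaries$hemisphere %in% pick)
  rows <- unlist(lapply(segs, function(s) (tde$seg_start[s] + 1):tde$seg_end[s]))
  n_rows <- tde$seg_end[segs] - tde$seg_start[segs]
  seg_end <- cumsum(n_rows)
  structure(list(Y = tde$Y[rows, , drop = FALSE], L = tde$L,
                 time_index = tde$time_index[rows],
                 seg_start = c(0, head(seg_end, -1)), seg_end = seg_end,
                 boundaries = boundaries[segs, ]),
            class = "tde_data")
}

#' Run the full state-dynamics analysis
#'
#' Orchestrates simulate (or load) -> preprocess -> TDE-HMM model grid ->
#' band assignment -> state/band features -> threshold comparator ->
#' ridge prediction -> permutation/FDR statistics, and returns one report
#' bundle. Per-model failures are isolated and reported; the run continues.
#'
#' @param config an [analysis_config()].
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return A list of class `analysis_report`; see the vignette for the
#'   layout.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- config$cohort
  if (inherits(cohort, "cohort_spec")) cohort <- simulate_cohort(cohort)

  concat <- preprocess_cohort(cohort)
  bands <- default_bands()
  envelopes <- band_envelopes(concat, bands = bands)
  scores <- hemibody_scores(cohort$scores)

  targets_y <- scores$pct_change
  hemis_y <- targets_y$hemisphere

  # ---- TDE-HMM arm over the model grid -------------------------------------
  grid <- config$model_grid
  models <- list()
  band_maps <- list()
  feat_tabs <- list()
  failures <- list()
  ridge_rows <- list()
  subset_rows <- list()
  coef_rows <- list()
  for (L in unique(grid$L)) {
    tde_full <- tryCatch(embed_delay(concat, L), error = function(e) e)
    if (inherits(tde_full, "error")) {
      for (K in grid$K[grid$L == L])
        failures[[sprintf("K%02d_L%02d", K, L)]] <- conditionMessage(tde_full)
      next
    }
    tde_fit <- fit_segment_subset(tde_full, concat$boundaries, config$fit_hemispheres)
    for (K in grid$K[grid$L == L]) {
      model_id <- sprintf("K%02d_L%02d", K, L)
      res <- tryCatch({
        cfg <- hmm_config(K, L, max_iter = config$max_iter, tol = config$tol,
                          n_restarts = config$n_restarts,
                          seed = derive_seed(config$seed, "hmm", K, L))
        m <- fit_hmm(tde_fit, cfg)
        m <- decode_states(m, tde_full)
        bmap <- assign_bands(m, envelopes)
        ft <- feature_table(m, bmap,
                            envelopes = if (config$amplitude_features) envelopes else NULL)
        ft <- rbind(ft, transition_feature_rows(m, bmap))
        list(model = m, bmap = bmap, ft = ft)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[model_id]] <- conditionMessage(res)
        next
      }
      models[[model_id]] <- res$model
      band_maps[[model_id]] <- res$bmap
      feat_tabs[[model_id]] <- res$ft

      # the regression uses the full pre-collapse state-level feature set
      # (plus the session switching rate); band-level rows enter only as
      # amplitude features when that augmentation is enabled
      dwell_feats <- c("fractional_occupancy", "life_time", "interval_time",
                       "occurrence_rate", "switching_rate")
      for (mode in config$modes) {
        des <- build_design(res$ft, mode, level = c("state", "session"),
                            features = if (!config$include_duration_bins) dwell_feats)
        if (config$amplitude_features) {
          amp <- build_design(res$ft, mode, level = "band", features = "amplitude")
          stopifnot(identical(des$hemisphere, amp$hemisphere))
          des$X <- cbind(des$X, amp$X)
          des$labels <- rbind(des$labels, amp$labels)
        }
        for (target in config$targets) {
          y_all <- targets_y[[target]]
          ok <- !is.na(y_all) & hemis_y %in% des$hemisphere
          rowsel <- match(hemis_y[ok], des$hemisphere)
          rm_ <- ridge_predict_scores(des$X[rowsel, , drop = FALSE], y_all[ok])
          ridge_rows[[paste(model_id, mode, target)]] <- data.frame(
            arm = "hmm", model_id = model_id, K = K, L = L, mode = mode,
            target = target, kappa = rm_$kappa, r2 = rm_$r2, r2_ss = rm_$r2_ss,
            n = rm_$n, p = rm_$p, stringsAsFactors = FALSE)
          if (mode == config$modes[1] && target == config$targets[1]) {
            coef_rows[[model_id]] <- cbind(model_id = model_id,
              band_coefficients(rm_$beta, des$labels, res$bmap))
          }
        }
      }

      if (config$do_subsets) {
        lb_states <- res$bmap$state[res$bmap$band == "low_beta"]
        other_states <- setdiff(res$bmap$state, lb_states)
        y_all <- targets_y[[config$targets[1]]]
        for (sub in c("low_beta_only", "non_low_beta")) {
          states <- if (sub == "low_beta_only") lb_states else other_states
          if (length(states) == 0) next
          des <- build_design(res$ft, config$modes[1], level = "state",
                              units = paste("state", states),
                              features = if (!config$include_duration_bins)
                                dwell_feats)
          if (ncol(des$X) == 0) next
          ok <- !is.na(y_all) & hemis_y %in% des$hemisphere
          rowsel <- match(hemis_y[ok], des$hemisphere)
          rm_ <- ridge_predict_scores(des$X[rowsel, , drop = FALSE], y_all[ok])
          subset_rows[[paste(model_id, sub)]] <- data.frame(
            arm = "hmm_subset", model_id = model_id, subset = sub,
            mode = config$modes[1], target = config$targets[1],
            kappa = rm_$kappa, r2 = rm_$r2, stringsAsFactors = FALSE)
        }
      }
    }
  }

  # ---- threshold comparator arm --------------------------------------------
  thr_tabs <- list()
  if (config$do_threshold) {
    env_by_session <- split_envelopes(envelopes, concat$boundaries)
    manifest <- concat$boundaries[, c("hemisphere", "condition")]
    for (pct in config$percentiles) {
      model_id <- sprintf("pct%02d", pct)
      ft <- threshold_feature_table(env_by_session, manifest, pct)
      thr_tabs[[model_id]] <- ft
      for (mode in config$modes) {
        # the comparator's feature set is burst rate, mean duration and
        # (optionally) the duration-binned relative counts; occupancy above
        # threshold is reported in the tables but is not part of the
        # standard burst feature set
        des <- build_design(ft, mode, level = "band",
                            features = c("rate", "mean_duration",
                                         if (config$include_duration_bins)
                                           grep("^relbursts_", unique(ft$feature), value = TRUE)))
        for (target in config$targets) {
          y_all <- targets_y[[target]]
          ok <- !is.na(y_all) & hemis_y %in% des$hemisphere
          rowsel <- match(hemis_y[ok], des$hemisphere)
          rm_ <- ridge_predict_scores(des$X[rowsel, , drop = FALSE], y_all[ok])
          ridge_rows[[paste(model_id, mode, target)]] <- data.frame(
            arm = "threshold", model_id = model_id, K = NA, L = NA, mode = mode,
            target = target, kappa = rm_$kappa, r2 = rm_$r2, r2_ss = rm_$r2_ss,
            n = rm_$n, p = rm_$p, stringsAsFactors = FALSE)
        }
      }
    }
  }

  ridge <- do.call(rbind, ridge_rows)
  rownames(ridge) <- NULL
  ridge_summary <- if (!is.null(ridge)) {
    stats::aggregate(r2 ~ arm + mode + target, data = ridge, FUN = stats::median)
  }

  # ---- delta statistics and bivariate correlation grid ---------------------
  stats_delta <- NULL
  bivariate <- NULL
  if (config$do_stats && length(feat_tabs)) {
    stats_delta <- delta_statistics(feat_tabs, config$n_perm,
                                    derive_seed(config$seed, "stats"))
    bivariate <- bivariate_grid(feat_tabs, targets_y, config$targets[1],
                                config$n_perm, derive_seed(config$seed, "biv"))
  }

  report <- structure(list(
    config = config, cohort_scores = scores,
    boundaries = concat$boundaries,
    selected_channels = attr(concat, "selected_channel"),
    band_maps = band_maps, feature_tables = feat_tabs,
    threshold_tables = thr_tabs,
    state_spectra = lapply(models, state_spectra),
    ridge = ridge, ridge_summary = ridge_summary,
    subset_ridge = if (length(subset_rows)) do.call(rbind, subset_rows),
    band_coefficients = if (length(coef_rows)) do.call(rbind, coef_rows),
    stats_delta = stats_delta, bivariate = bivariate,
    failures = failures,
    truth = cohort$truth), class = "analysis_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Cross-model permutation tests on band-level ON-OFF deltas: each model
# contributes its median delta across hemispheres per (band, feature) cell
# (occurrence rate, fractional occupancy, life/interval time, transition
# probabilities); cells are FDR-corrected together.
delta_statistics <- function(feat_tabs, n_perm, seed, q = 0.05) {
  cells <- list()
  for (model_id in names(feat_tabs)) {
    ft <- feat_tabs[[model_id]]
    d <- ft[ft$condition == "delta" & ft$level %in% c("band", "transition") &
              ft$feature %in% c("fractional_occupancy", "life_time",
                                "interval_time", "occurrence_rate", "trans_prob"), ]
    agg <- stats::aggregate(value ~ level + unit + feature, data = d,
                            FUN = stats::median, na.action = stats::na.omit)
    agg$model_id <- model_id
    cells[[model_id]] <- agg
  }
  all <- do.call(rbind, cells)
  keys <- unique(all[, c("level", "unit", "feature")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- all$level == keys$level[i] & all$unit == keys$unit[i] &
      all$feature == keys$feature[i]
    v <- all$value[sel]
    pt <- paired_permutation_test(v[!is.na(v)], n_perm = n_perm,
                                  seed = derive_seed(seed, keys$unit[i], keys$feature[i]))
    out[[i]] <- data.frame(level = keys$level[i], unit = keys$unit[i],
                           feature = keys$feature[i], n_models = sum(!is.na(v)),
                           median_delta = stats::median(v, na.rm = TRUE),
                           statistic = pt$statistic, p = pt$p,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  fdr <- fdr_bh(res$p, q)
  res$p_adjusted <- fdr$p_adjusted
  res$rejected <- fdr$rejected
  res
}

# Per-model bivariate (Spearman) correlations between band-level feature
# deltas and percentage score change, with cross-model sign-consistency
# tests and FDR over cells.
bivariate_grid <- function(feat_tabs, targets_y, target, n_perm, seed, q = 0.05) {
  y <- targets_y[[target]]
  hemi_y <- targets_y$hemisphere
  rows <- list()
  for (model_id in names(feat_tabs)) {
    ft <- feat_tabs[[model_id]]
    d <- ft[ft$condition == "delta" & ft$level == "band" &
              ft$feature %in% c("occurrence_rate", "fractional_occupancy",
                                "life_time", "interval_time"), ]
    for (b in unique(d$unit)) for (f in unique(d$feature)) {
      v <- d[d$unit == b & d$feature == f, ]
      m <- match(hemi_y, v$hemisphere)
      rows[[paste(model_id, b, f)]] <- data.frame(
        model_id = model_id, band = b, feature = f,
        rho = bivariate_corr(v$value[m], y), stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, rows)
  keys <- unique(all[, c("band", "feature")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    r <- all$rho[all$band == keys$band[i] & all$feature == keys$feature[i]]
    sc <- sign_consistency_test(r, n_perm = n_perm,
                                seed = derive_seed(seed, keys$band[i], keys$feature[i]))
    out[[i]] <- data.frame(band = keys$band[i], feature = keys$feature[i],
                           n_models = sum(!is.na(r)), median_rho = sc$statistic,
                           p = sc$p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  fdr <- fdr_bh(res$p, q)
  res$p_adjusted <- fdr$p_adjusted
  res$rejected <- fdr$rejected
  list(per_model = all, cells = res)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("State-dynamics analysis report\n")
  cat(sprintf("  %d HMM models (%d failed), %d threshold models\n",
              length(x$feature_tables), length(x$failures), length(x$threshold_tables)))
  if (!is.null(x$ridge_summary)) {
    cat("  median LOOCV r2 by arm:\n")
    print(x$ridge_summary, row.names = FALSE)
  }
  invisible(x)
}

# Write the report's tabular pieces and a reproducibility manifest.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, name) if (!is.null(d)) utils::write.csv(d, file.path(out_dir, name), row.names = FALSE)
  wr(report$ridge, "ridge_r2.csv")
  wr(report$ridge_summary, "ridge_summary.csv")
  wr(report$subset_ridge, "ridge_subsets.csv")
  wr(report$stats_delta, "delta_statistics.csv")
  if (!is.null(report$bivariate)) {
    wr(report$bivariate$cells, "bivariate_cells.csv")
    wr(report$bivariate$per_model, "bivariate_per_model.csv")
  }
  wr(report$band_coefficients, "band_coefficients.csv")
  for (m in names(report$feature_tables))
    wr(report$feature_tables[[m]], sprintf("features_%s.csv", m))
  for (m in names(report$band_maps))
    wr(as.data.frame(report$band_maps[[m]]), sprintf("bandmap_%s.csv", m))
  manifest <- list(package_version = as.character(utils::packageVersion("lfpstates")),
                   seed = report$config$seed,
                   model_grid = report$config$model_grid,
                   percentiles = report$config$percentiles,
                   failures = report$failures)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
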