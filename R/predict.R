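#' Hemibody clinical scores from UPDRS sub-items
#'
#' Bradykinesia-rigidity is the sum of motor sub-items 22-26, tremor the sum
#' of sub-items 20-21; total is their sum. Percentage change is
#' `100 * (OFF - ON) / OFF` per component (positive = improvement ON), and is
#' missing where the OFF score is zero. Hemispheres with missing items are
#' flagged and excluded.
#'
#' @param items data.frame with columns `hemisphere`, `condition`
#'   (`OFF`/`ON`) and `item20` ... `item26` (non-negative integers).
#' @return A list with `scores` (hemisphere, condition, bradyrigid, tremor,
#'   total), `pct_change` (hemisphere, bradyrigid, tremor, total) and
#'   `excluded` (hemisphere ids dropped for missing items).
#' @export
hemibody_scores <- function(items) {
  item_cols <- paste0("item", 20:26)
  missing_any <- !stats::complete.cases(items[, item_cols])
  excluded <- unique(items$hemisphere[missing_any])
  ok <- !(items$hemisphere %in% excluded)
  it <- items[ok, , drop = FALSE]
  scores <- data.frame(
    hemisphere = it$hemisphere, condition = it$condition,
    tremor = it$item20 + it$item21,
    bradyrigid = it$item22 + it$item23 + it$item24 + it$item25 + it$item26,
    stringsAsFactors = FALSE)
  scores$total <- scores$bradyrigid + scores$tremor
  off <- scores[scores$condition == "OFF", ]
  on <- scores[scores$condition == "ON", ]
  m <- match(off$hemisphere, on$hemisphere)
  pct <- function(comp) {
    o <- off[[comp]]
    n <- on[[comp]][m]
    ifelse(o > 0, 100 * (o - n) / o, NA_real_)
  }
  pct_change <- data.frame(hemisphere = off$hemisphere,
                           bradyrigid = pct("bradyrigid"),
                           tremor = pct("tremor"), total = pct("total"),
                           stringsAsFactors = FALSE)
  list(scores = scores, pct_change = pct_change, excluded = excluded)
}

#' Build a regression design matrix from a tidy feature table
#'
#' One row per hemisphere; one column per (unit, feature). `mode = "delta"`
#' uses the ON-OFF delta rows, `mode = "off"` the OFF-condition values.
#' Missing cells are imputed by the column median (logged); all-missing and
#' constant columns are dropped with a warning-free record.
#'
#' @param tab tidy feature table ([feature_table()] or
#'   [threshold_feature_table()]).
#' @param mode `"delta"` or `"off"`.
#' @param level restrict to feature rows of this level (`"state"`, `"band"`,
#'   `"session"`); `NULL` keeps all.
#' @param units optional unit subset (e.g. the states of one band).
#' @param features optional feature-name subset, matched per level as
#'   `"<level>:<feature>"` entries or plain feature names.
#' @return A list with `X` (n x p numeric matrix, unstandardized),
#'   `hemisphere` row ids, `labels` (data.frame unit, feature per column),
#'   `dropped` and `imputed` bookkeeping.
#' @export
build_design <- function(tab, mode = c("delta", "off"), level = NULL,
                         units = NULL, features = NULL) {
  mode <- match.arg(mode)
  cond <- if (mode == "delta") "delta" else "OFF"
  d <- tab[tab$condition == cond, , drop = FALSE]
  if (!is.null(level)) d <- d[d$level %in% level, , drop = FALSE]
  if (!is.null(units)) d <- d[paste(d$level, d$unit) %in% units, , drop = FALSE]
  if (!is.null(features))
    d <- d[d$feature %in% features | paste0(d$level, ":", d$feature) %in% features, , drop = FALSE]
  d$col <- paste(d$level, d$unit, d$feature, sep = ".")
  hemis <- sort(unique(d$hemisphere))
  cols <- unique(d$col)
  X <- matrix(NA_real_, length(hemis), length(cols),
              dimnames = list(hemis, cols))
  X[cbind(match(d$hemisphere, hemis), match(d$col, cols))] <- d$value
  # impute column medians, drop all-missing and constant columns
  imputed <- character(0)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas) && !all(nas)) {
      X[nas, j] <- stats::median(X[, j], na.rm = TRUE)
      imputed <- c(imputed, cols[j])
    }
  }
  keep <- apply(X, 2, function(v) !any(is.na(v)) && stats::sd(v) > 0)
  dropped <- cols[!keep]
  X <- X[, keep, drop = FALSE]
  first <- d[!duplicated(d$col), c("col", "level", "unit", "feature")]
  labels <- first[match(colnames(X), first$col), c("level", "unit", "feature")]
  rownames(labels) <- NULL
  list(X = X, hemisphere = hemis, labels = labels,
       dropped = dropped, imputed = unique(imputed))
}

#' Ridge regression coefficients
#'
#' Exact solve of `(X'X + kappa I) beta = X'y` by a stable linear solve (no
#' explicit inverse). With `kappa = 0` this is ordinary least squares and
#' requires a full-rank system.
#'
#' @param X n x p design matrix.
#' @param y length-n response.
#' @param kappa ridge penalty (>= 0).
#' @return Length-p coefficient vector.
#' @export
ridge_fit <- function(X, y, kappa) {
  stopifnot_finite(X, "X")
  stopifnot_finite(y, "y")
  if (kappa < 0) stop("kappa must be >= 0")
  X <- as.matrix(X)
  G <- crossprod(X) + diag(kappa, ncol(X))
  if (kappa == 0 && (ncol(X) > nrow(X) || rcond(G) < 1e-12))
    stop("singular system at kappa = 0; use kappa > 0")
  as.numeric(solve(G, crossprod(X, y)))
}

# Standardize columns; constant columns get sd 1 (they are centered to 0).
std_fit <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0] <- 1
  list(mu = mu, s = s)
}
std_apply <- function(X, f) sweep(sweep(X, 2, f$mu), 2, f$s, "/")

#' Leave-one-out cross-validated ridge predictions
#'
#' For each observation the model is refitted on the remaining rows
#' (re-standardizing predictors and response within the training fold) and
#' the held-out row predicted; `r2` is the squared Pearson correlation
#' between out-of-fold predictions and the actual response, set to 0 when
#' the predictions have zero variance or correlate negatively with the
#' response (in the strong-shrinkage limit leave-one-out predictions
#' approach the training-fold mean, which is exactly anti-correlated with
#' the held-out value; an unsigned square would read that artifact as
#' perfect prediction). `r2_ss = 1 - SSE/SST` is also reported.
#'
#' @param X n x p design matrix (unstandardized).
#' @param y length-n response.
#' @param kappa ridge penalty.
#' @return A list with `predictions`, `r2`, `r2_ss`, `flagged`.
#' @export
loocv_ridge <- function(X, y, kappa) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("LOOCV needs n >= 3")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    fx <- std_fit(Xi)
    my <- mean(yi)
    sy <- stats::sd(yi)
    if (sy == 0) sy <- 1
    # SVD form of the ridge solution: stable for tiny penalties and p > n
    sv <- svd(std_apply(Xi, fx))
    shrink <- ifelse(sv$d > 0, sv$d / (sv$d^2 + kappa), 0)
    w <- shrink * crossprod(sv$u, (yi - my) / sy)
    beta <- sv$v %*% w
    pred[i] <- my + sy * sum(as.numeric(std_apply(X[i, , drop = FALSE], fx)) * as.numeric(beta))
  }
  flagged <- stats::sd(pred) == 0
  r <- if (flagged) 0 else stats::cor(pred, y)
  list(predictions = pred, r2 = max(0, r)^2,
       r2_ss = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
       flagged = flagged)
}

#' Select the ridge penalty on a power-of-two grid
#'
#' The default grid is `2^v` for `v` in -30 ... 30. Prediction power is
#' measured by the out-of-fold skill `1 - SSE/SST` (monotone equivalent of
#' the LOOCV mean squared error; unlike an unsigned squared correlation it
#' cannot reward the anti-correlated strong-shrinkage limit). The penalty
#' maximizing the skill is found, then the selection extends to the
#' smallest `kappa` whose skill is within `tol_r2` of that maximum (the
#' "prediction power converged" reading). Deterministic.
#'
#' @param X,y design and response.
#' @param grid candidate penalties.
#' @param tol_r2 convergence tolerance on the skill.
#' @return A list with `kappa`, `r2_path` (out-of-fold skill per grid
#'   point) and `best_r2`.
#' @export
select_kappa <- function(X, y, grid = 2^(-30:30), tol_r2 = 0.005) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("LOOCV needs n >= 3")
  # precompute per-fold SVDs of the standardized training matrices so the
  # whole grid costs one decomposition per fold
  folds <- lapply(seq_len(n), function(i) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    fx <- std_fit(Xi)
    my <- mean(yi)
    sy <- stats::sd(yi)
    if (sy == 0) sy <- 1
    sv <- svd(std_apply(Xi, fx))
    list(uty = crossprod(sv$u, (yi - my) / sy), dvec = sv$d, v = sv$v,
         x0 = std_apply(X[i, , drop = FALSE], fx), my = my, sy = sy)
  })
  sst <- sum((y - mean(y))^2)
  # predictions for the whole grid at once: per fold, project the held-out
  # row on the right singular vectors and shrink spectrally
  preds <- vapply(folds, function(f) {
    a <- as.numeric(f$x0 %*% f$v) * as.numeric(f$uty)
    shrink <- outer(f$dvec, grid, function(dd, kk) ifelse(dd > 0, dd / (dd^2 + kk), 0))
    f$my + f$sy * as.numeric(a %*% shrink)
  }, numeric(length(grid)))
  preds <- matrix(preds, nrow = length(grid)) # grid points x folds
  r2_path <- 1 - colSums((y - t(preds))^2) / sst
  best <- max(r2_path)
  kappa <- grid[which(r2_path >= best - tol_r2)[1]]
  list(kappa = kappa, r2_path = r2_path, best_r2 = best)
}

#' Fit the full ridge prediction for one model's features
#'
#' Penalty selection ([select_kappa()]) followed by LOOCV under the selected
#' penalty and a final full-data fit of the standardized coefficients.
#'
#' @param X design matrix from [build_design()].
#' @param y response (e.g. percentage score change).
#' @param grid penalty grid.
#' @return An object of class `ridge_model`: `kappa`, `beta` (standardized
#'   coefficients), `loocv_pred`, `r2`, `r2_ss`, `labels` when present on X.
#' @export
ridge_predict_scores <- function(X, y, grid = 2^(-30:30)) {
  sel <- select_kappa(X, y, grid)
  cv <- loocv_ridge(X, y, sel$kappa)
  fx <- std_fit(X)
  my <- mean(y)
  sy <- stats::sd(y)
  beta <- ridge_fit(std_apply(X, fx), (y - my) / sy, sel$kappa)
  structure(list(kappa = sel$kappa, beta = beta, loocv_pred = cv$predictions,
                 r2 = cv$r2, r2_ss = cv$r2_ss, flagged = cv$flagged,
                 kappa_r2_path = sel$r2_path, n = nrow(as.matrix(X)),
                 p = ncol(as.matrix(X))),
            class = "ridge_model")
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("Ridge model: n = %d, p = %d, kappa = %g\n", x$n, x$p, x$kappa))
  cat(sprintf("  LOOCV r2 = %.3f (1 - SSE/SST = %.3f)\n", x$r2, x$r2_ss))
  invisible(x)
}

#' Summarise ridge coefficients by frequency band
#'
#' Standardized coefficients of state-level features are grouped by the
#' band their state is assigned to; the summary per (band, feature type) is
#' the median, sign retained.
#'
#' @param beta standardized coefficient vector.
#' @param labels data.frame (level, unit, feature) per coefficient.
#' @param band_map a `band_map` (state -> band).
#' @return data.frame band, feature, median_coefficient, n_coefficients.
#' @export
band_coefficients <- function(beta, labels, band_map) {
  st <- labels$level == "state"
  band <- rep(NA_character_, length(beta))
  band[st] <- band_map$band[as.integer(labels$unit[st])]
  d <- data.frame(band = band[st], feature = labels$feature[st], beta = beta[st],
                  stringsAsFactors = FALSE)
  agg <- stats::aggregate(beta ~ band + feature, data = d, FUN = stats::median)
  cnt <- stats::aggregate(beta ~ band + feature, data = d, FUN = length)
  data.frame(band = agg$band, feature = agg$feature,
             median_coefficient = agg$beta, n_coefficients = cnt$beta,
             stringsAsFactors = FALSE)
}
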