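#' Sign-flip permutation test on paired deltas
#'
#' Tests the mean of per-unit ON-OFF deltas against zero by randomly flipping
#' the sign of each delta. When `2^n <= n_perm` all sign patterns are
#' enumerated exactly; otherwise `n_perm` Monte-Carlo flips are drawn under
#' the seed. Two-sided by default.
#'
#' @param deltas numeric vector of paired differences.
#' @param n_perm number of permutations (>= 1000 recommended).
#' @param seed seed for the Monte-Carlo branch.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A list with `p`, `statistic` (observed mean), `exact`.
#' @export
paired_permutation_test <- function(deltas, n_perm = 5000, seed = 1L,
                                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  deltas <- deltas[!is.na(deltas)]
  n <- length(deltas)
  obs <- mean(deltas)
  if (all(deltas == 0)) return(list(p = 1, statistic = obs, exact = TRUE))
  exact <- 2^n <= n_perm
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- as.numeric(signs %*% deltas) / n
    denom <- nrow(signs)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    stat <- as.numeric(signs %*% deltas) / n
    # include the observed statistic among the draws (guards p = 0)
    stat <- c(obs, stat)
    denom <- n_perm + 1
  }
  tol <- 1e-12 * max(1, abs(obs))
  p <- switch(alternative,
    two.sided = sum(abs(stat) >= abs(obs) - tol) / denom,
    greater = sum(stat >= obs - tol) / denom,
    less = sum(stat <= obs + tol) / denom)
  list(p = p, statistic = obs, exact = exact)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure at level `q`; adjusted p-values are monotone after the
#' step-up enforcement (via [stats::p.adjust()]).
#'
#' @param pvals p-values in `[0, 1]` (`NA` allowed, never rejected).
#' @param q FDR level.
#' @return A list with `rejected` (logical mask) and `p_adjusted`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(rejected = logical(0), p_adjusted = numeric(0)))
  adj <- stats::p.adjust(pvals, method = "BH")
  list(rejected = !is.na(adj) & adj <= q, p_adjusted = adj)
}

#' Sign-consistency test across HMM models
#'
#' For a fixed (band, feature, duration-bin) cell, tests whether the
#' per-model correlations are consistently more positive or negative than
#' zero, by sign-flip permutation. The permutation statistic is the mean of
#' the per-model correlations (a median statistic is degenerate under sign
#' flips at these small model counts); the median is reported descriptively.
#' FDR correction across cells is the caller's responsibility.
#'
#' @param correlations one correlation per HMM model.
#' @param n_perm,seed as in [paired_permutation_test()].
#' @return A list with `p` (`NA` with fewer than 3 models), `statistic`
#'   (median of the correlations), `exact`.
#' @export
sign_consistency_test <- function(correlations, n_perm = 5000, seed = 1L) {
  r <- correlations[!is.na(correlations)]
  n <- length(r)
  if (n < 3) return(list(p = NA_real_, statistic = NA_real_, exact = NA))
  res <- paired_permutation_test(r, n_perm = n_perm, seed = seed)
  list(p = res$p, statistic = stats::median(r), exact = res$exact)
}

#' Bivariate correlation between a feature change and score change
#'
#' Spearman by default (Pearson by argument); missing pairs are dropped
#' pairwise; missing result on zero variance or fewer than 3 pairs.
#'
#' @param x,y paired numeric vectors.
#' @param method `"spearman"` or `"pearson"`.
#' @return Scalar correlation or `NA`.
#' @export
bivariate_corr <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok], method = method)
}
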