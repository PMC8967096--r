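test_that("hemibody scores sum the right sub-items", {
  items <- data.frame(hemisphere = rep(c("a", "b"), each = 2),
                      condition = rep(c("OFF", "ON"), 2),
                      item20 = c(1, 0, 2, 1), item21 = c(1, 1, 0, 0),
                      item22 = 2, item23 = 2, item24 = 2, item25 = 2, item26 = 2)
  hs <- hemibody_scores(items)
  expect_equal(hs$scores$bradyrigid, rep(10, 4))
  expect_equal(hs$scores$tremor, c(2, 1, 2, 1))
  expect_equal(hs$scores$total, hs$scores$bradyrigid + hs$scores$tremor)
  # OFF 12, ON 11 for hemisphere a
  expect_equal(hs$pct_change$total[hs$pct_change$hemisphere == "a"],
               100 * (12 - 11) / 12)

  # OFF 20, ON 10 gives 50%
  it2 <- data.frame(hemisphere = "c", condition = c("OFF", "ON"),
                    item20 = 0, item21 = 0, item22 = c(4, 2), item23 = c(4, 2),
                    item24 = c(4, 2), item25 = c(4, 2), item26 = c(4, 2))
  expect_equal(hemibody_scores(it2)$pct_change$total, 50)

  # zero OFF score: percentage change undefined
  it3 <- it2
  it3[, paste0("item", 20:26)] <- 0
  expect_true(is.na(hemibody_scores(it3)$pct_change$total))

  # missing item excludes the hemisphere with a flag
  it4 <- it2
  it4$item24[1] <- NA
  hs4 <- hemibody_scores(it4)
  expect_equal(hs4$excluded, "c")
  expect_equal(nrow(hs4$scores), 0)
})

test_that("design matrices have the documented shape and drop rules", {
  tab <- data.frame(
    hemisphere = rep(c("a", "b", "c"), each = 4),
    condition = "delta", level = "state",
    unit = rep(c("1", "1", "2", "2"), 3),
    feature = rep(c("fractional_occupancy", "life_time"), 6),
    value = c(1, 2, 3, 4, 2, 3, 4, 5, 3, 4, 5, 6))
  des <- build_design(tab, "delta")
  expect_equal(dim(des$X), c(3, 4))
  expect_equal(des$hemisphere, c("a", "b", "c"))

  # constant column dropped
  tab2 <- tab
  tab2$value[tab2$unit == "1" & tab2$feature == "life_time"] <- 7
  des2 <- build_design(tab2, "delta")
  expect_equal(ncol(des2$X), 3)
  expect_true(any(grepl("life_time", des2$dropped)))

  # missing cell imputed by the column median
  tab3 <- tab
  tab3$value[1] <- NA
  des3 <- build_design(tab3, "delta")
  expect_equal(des3$X["a", "state.1.fractional_occupancy"],
               median(tab3$value[tab3$unit == "1" &
                                 tab3$feature == "fractional_occupancy"], na.rm = TRUE))
  expect_length(des3$imputed, 1)

  # all-identical OFF/ON features: delta design collapses entirely
  tab4 <- tab
  tab4$value <- 0
  des4 <- build_design(tab4, "delta")
  expect_equal(ncol(des4$X), 0)
  expect_error(ridge_predict_scores(des4$X, rnorm(3)))
})

test_that("ridge solutions match closed forms", {
  # orthonormal columns at kappa = 0 reduce to OLS = X'y
  q <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
  y <- rnorm(10)
  expect_equal(ridge_fit(q, y, 0), as.numeric(crossprod(q, y)), tolerance = 1e-8)

  # hand-computed toy: X = [1; 1], y = (1, 3), kappa = 2 -> beta = 4 / (2 + 2)
  expect_equal(ridge_fit(matrix(1, 2, 1), c(1, 3), 2), 1.0)

  # strong shrinkage sends coefficients to zero
  X <- matrix(rnorm(40), 20, 2)
  expect_lt(sqrt(sum(ridge_fit(X, rnorm(20), 1e6)^2)), 1e-3)

  # OLS equivalence on a full-rank toy
  X2 <- cbind(1, matrix(rnorm(60), 20, 3))
  y2 <- rnorm(20)
  expect_equal(ridge_fit(X2, y2, 0), as.numeric(coef(lm.fit(X2, y2))), tolerance = 1e-8)

  expect_error(ridge_fit(matrix(rnorm(6), 2, 3), rnorm(2), 0), "singular")
  expect_error(ridge_fit(X, rnorm(20), -1), "kappa")
})

test_that("coefficient norms shrink monotonically in kappa", {
  set.seed(31)
  X <- matrix(rnorm(200), 40, 5)
  y <- X[, 1] - X[, 3] + rnorm(40)
  norms <- sapply(2^(-10:10), function(k) sqrt(sum(ridge_fit(X, y, k)^2)))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("LOOCV predicts noiseless linear responses nearly perfectly", {
  set.seed(32)
  X <- matrix(rnorm(320), 64, 5)
  y <- 2 * X[, 2]
  cv <- loocv_ridge(X, y, 1e-6)
  expect_gte(cv$r2, 0.999)
  expect_length(cv$predictions, 64)

  cv3 <- loocv_ridge(matrix(rnorm(9), 3, 3), rnorm(3), 1)
  expect_length(cv3$predictions, 3)
  expect_error(loocv_ridge(matrix(rnorm(4), 2, 2), rnorm(2), 1), "n >= 3")
})

test_that("null responses yield near-zero cross-validated r2", {
  set.seed(33)
  r2s <- replicate(100, {
    X <- matrix(rnorm(64 * 10), 64, 10)
    loocv_ridge(X, rnorm(64), 1)$r2
  })
  expect_lte(mean(r2s), 0.08)
})

test_that("penalty selection favors shrinkage under the null and signal when present", {
  set.seed(34)
  # pure noise: selected kappa in the upper half of the grid
  grid <- 2^(-30:30)
  upper <- 0
  for (i in 1:20) {
    X <- matrix(rnorm(64 * 10), 64, 10)
    k <- select_kappa(X, rnorm(64), grid)$kappa
    if (log2(k) >= 0) upper <- upper + 1
  }
  expect_gte(upper / 20, 0.8)

  # strong low-dimensional signal with n >> p: little shrinkage needed
  small <- 0
  for (i in 1:10) {
    X <- matrix(rnorm(64 * 3), 64, 3)
    y <- 3 * X[, 1] + 0.1 * rnorm(64)
    k <- select_kappa(X, y, grid)$kappa
    if (k <= 1) small <- small + 1
  }
  expect_gte(small / 10, 0.8)

  expect_equal(select_kappa(matrix(rnorm(30), 10, 3), rnorm(10), grid = 4)$kappa, 4)
})

test_that("ridge coefficients summarize by band with sign retained", {
  labels <- data.frame(level = rep("state", 4), unit = c("1", "2", "3", "4"),
                       feature = rep("occurrence_rate", 4))
  bm <- data.frame(state = 1:4, band = c("low_beta", "low_beta", "theta", "theta"))
  bc <- band_coefficients(c(0.5, 0.3, -0.2, -0.4), labels, bm)
  expect_equal(bc$median_coefficient[bc$band == "low_beta"], 0.4)
  expect_equal(bc$median_coefficient[bc$band == "theta"], -0.3)

  # symmetric pair medians to zero
  bc2 <- band_coefficients(c(0.2, -0.2), labels[1:2, ],
                           data.frame(state = 1:2, band = "alpha"))
  expect_equal(bc2$median_coefficient, 0)
})
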