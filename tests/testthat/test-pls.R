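test_that("PLS-1 recovers exact linear relations and matches OLS at full rank", {
  set.seed(23)
  X <- matrix(rnorm(20 * 6), 20)
  ## y exactly linear in one column, one latent variable suffices
  y1 <- 3 + 2 * X[, 4]
  m1 <- fit_pls(X[, 4, drop = FALSE], y1, 1)
  expect_lt(sqrt(mean(residuals(m1)^2)), 1e-10)
  expect_equal(stats::cor(fitted(m1), y1), 1, tolerance = 1e-10)

  ## full rank: predictions equal least squares
  y <- rnorm(20)
  m <- fit_pls(X, y, 6)
  ols_fit <- drop(cbind(1, X) %*% stats::lm.fit(cbind(1, X), y)$coefficients)
  expect_lt(max(abs(fitted(m) - ols_fit)), 1e-8)

  ## first weight vector is proportional to the centered cross-covariance
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  w1 <- m$weights[, 1]
  v <- drop(crossprod(Xc, yc))
  expect_equal(abs(sum(w1 * v)) / sqrt(sum(w1^2) * sum(v^2)), 1,
               tolerance = 1e-10)

  ## n_lv beyond the effective rank is rejected
  Xr <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(fit_pls(Xr, rnorm(20), 3), "rank")
})

test_that("predicting the training-mean spectrum returns y_mean exactly", {
  set.seed(24)
  X <- matrix(rnorm(30 * 50), 30)
  y <- rnorm(30, 10)
  for (a in c(1, 3, 7)) {
    m <- fit_pls(X, y, a)
    p <- predict(m, rbind(colMeans(X)))
    expect_equal(as.numeric(p), mean(y), tolerance = 1e-10)
  }
})

test_that("sqrt-transformed models predict on the original scale", {
  set.seed(25)
  X <- matrix(rnorm(60 * 10), 60)
  y <- exp(1 + X[, 1])                       # right-skewed, positive
  m <- fit_pls(X, y, 3, sqrt_transform = TRUE)
  expect_true(m$sqrt_transformed)
  expect_true(all(fitted(m) >= 0))
  p <- predict(m, X[1:5, ])
  expect_true(all(p >= 0))
  expect_equal(length(attr(p, "out_of_range")), 5)
  expect_error(fit_pls(X, y - 10, 2, sqrt_transform = TRUE), "non-negative")
})

test_that("latent-variable selection finds the generating rank", {
  ## noiseless rank-1 relation: X spanned by one latent direction
  set.seed(26)
  t1 <- rnorm(40)
  X1 <- outer(t1, rnorm(8))
  y1 <- 2 + 3 * t1
  expect_equal(as.integer(select_n_lv(X1, y1, seed = 3)), 1L)

  ## three latent factors plus mild noise
  set.seed(42)
  n <- 60; p <- 40
  T3 <- matrix(rnorm(n * 3), n)
  X3 <- T3 %*% matrix(rnorm(3 * p), 3) + matrix(rnorm(n * p, 0, 0.05), n)
  y3 <- T3 %*% c(1, -2, 1.5) + rnorm(n, 0, 0.05)
  sel <- as.integer(select_n_lv(X3, y3, seed = 5))
  expect_true(abs(sel - 3) <= 1)

  ## contract: always inside the search range
  expect_true(sel %in% 1:15)
  expect_error(select_n_lv(X1, rep(1, 40)), "zero variance")
})

test_that("validation metrics match hand computation and anchor cases", {
  ## perfect prediction
  perf <- validation_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perf$Q2, 1)
  expect_equal(perf$RMSE, 0)
  expect_equal(perf$CV_pct, 0)
  expect_equal(perf$R, 1)

  ## hand-computed case
  h <- validation_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(h$RMSE, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(h$Q2, 0.5, tolerance = 1e-12)
  expect_equal(h$CV_pct, 100 * sqrt(1 / 3) / 2, tolerance = 1e-12)

  ## the mean predictor anchors Q2 at exactly 0
  y <- c(4, 5, 7, 9)
  m0 <- validation_metrics(y, rep(mean(y), 4))
  expect_equal(m0$Q2, 0)
  expect_true(is.na(m0$R))

  expect_error(validation_metrics(rep(2, 5), 1:5), "zero variance")
  expect_error(validation_metrics(1:3, 1:4), "equal-length")
})

test_that("permutation test hits its floor for strong signal and obeys bounds", {
  set.seed(27)
  X <- matrix(rnorm(50 * 12), 50)
  y <- X %*% rnorm(12) + rnorm(50, 0, 0.01)
  pt <- permutation_test(X, y, n_lv = 5, B = 99, seed = 2)
  expect_equal(pt$p, 1 / 100)                 # beats every permutation
  expect_equal(length(pt$null_stats), 99)
  expect_gte(pt$p, 1 / (pt$B + 1))
  expect_gt(pt$observed, max(pt$null_stats))

  ## pure noise: p clearly non-significant for this draw
  y0 <- rnorm(50)
  pt0 <- permutation_test(X, y0, n_lv = 3, B = 99, seed = 4)
  expect_gt(pt0$p, 0.05)
})

test_that("cross-validation folds are seeded, balanced and exhaustive", {
  f <- make_folds(42, 10, seed = 7)
  expect_equal(length(f), 10)
  expect_setequal(unlist(f), 1:42)
  expect_true(max(lengths(f)) - min(lengths(f)) <= 1)
  expect_identical(f, make_folds(42, 10, seed = 7))
  expect_false(identical(f, make_folds(42, 10, seed = 8)))
})
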