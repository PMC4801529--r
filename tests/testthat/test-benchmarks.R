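# Benchmark models: MLR, classical SIMPLS, RBF LSSVM, tuning, evaluation.

test_that("MLR solves simple systems and refuses rank deficiency", {
  m <- mlr_fit(matrix(c(1, 2, 3), ncol = 1), c(2, 4, 6))
  expect_equal(m$coefficients, 2, tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-10)

  set.seed(81)
  X <- matrix(rnorm(10), 5, 2)
  mc <- mlr_fit(X, rep(7, 5))
  expect_equal(mc$coefficients, c(0, 0), tolerance = 1e-10)
  expect_equal(mc$intercept, 7)

  # normal equations: residuals orthogonal to the columns
  y <- rnorm(5)
  mr <- mlr_fit(X, y)
  expect_lt(max(abs(crossprod(X, mr$residuals))), 1e-8)

  expect_error(mlr_fit(cbind(X, X[, 1]), y), "rank deficient")
})

test_that("SIMPLS nests MLR at full rank and survives collinearity", {
  set.seed(82)
  X <- matrix(rnorm(30 * 4), 30, 4); y <- rnorm(30, X[, 1] - X[, 3])
  expect_lt(max(abs(simpls_fit(X, y, 4)$coefficients -
                    mlr_fit(X, y)$coefficients)), 1e-8)

  Xdup <- cbind(X[, 1], X[, 1])
  expect_error(mlr_fit(Xdup, y), "rank deficient")
  expect_s3_class(simpls_fit(Xdup, y, 1), "simpls_model")

  x1 <- matrix(rnorm(20), ncol = 1)
  y1 <- rnorm(20, 2 * x1)
  expect_equal(simpls_fit(x1, y1, 1)$coefficients,
               unname(coef(lm(y1 ~ x1))[2]), tolerance = 1e-10)
})

test_that("the LSSVM solution satisfies its defining linear system", {
  set.seed(83)
  X <- matrix(rnorm(20 * 3), 20, 3); y <- rnorm(20)
  m <- lssvm_fit(X, y, reg_gamma = 10, kernel_width = 5)
  Xs <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  K <- exp(-as.matrix(dist(Xs))^2 / 5)
  A <- rbind(c(0, rep(1, 20)), cbind(1, K + diag(20) / 10))
  resid <- A %*% c(m$bias, m$alphas) - c(0, y)
  expect_lt(max(abs(resid)), 1e-8 * sqrt(sum(y^2)))
})

test_that("large regularization makes the LSSVM interpolate", {
  set.seed(84)
  X <- matrix(rnorm(5 * 2), 5, 2); y <- rnorm(5)
  m <- lssvm_fit(X, y, reg_gamma = 1e8, kernel_width = 2)
  expect_lt(max(abs(predict(m, X) - y)), 1e-4)

  m1 <- lssvm_fit(matrix(1, 1, 1), 3.3, reg_gamma = 1e8, kernel_width = 1)
  expect_equal(predict(m1, matrix(1, 1, 1)), 3.3, tolerance = 1e-4)
})

test_that("LSSVM tuning returns the grid argmin", {
  set.seed(85)
  X <- matrix(rnorm(25 * 3), 25, 3); y <- rnorm(25, X[, 1])
  ds <- etongue_dataset(X, y)

  one <- tune_lssvm(ds, grid = list(reg_gamma = 10, kernel_width = 3))
  expect_equal(one$reg_gamma, 10); expect_equal(one$kernel_width, 3)

  grid <- list(reg_gamma = c(1, 100), kernel_width = c(1, 10))
  tuned <- tune_lssvm(ds, grid = grid, seed = 85)
  # independent exhaustive recomputation
  best <- Inf
  for (g in grid$reg_gamma) for (w in grid$kernel_width) {
    r <- weighted_rmse(y, loocv_predictions(
      ds, "lssvm", hyper = list(reg_gamma = g, kernel_width = w), seed = 85))
    if (r < best) { best <- r; bg <- g; bw <- w }
  }
  expect_equal(tuned$rmsecv, best)
  expect_equal(tuned$reg_gamma, bg)
  expect_equal(tuned$kernel_width, bw)

  # on clean linear data a tuned LSSVM is competitive with MLR
  full <- tune_lssvm(ds, seed = 85)
  mlr_rms <- weighted_rmse(y, loocv_predictions(ds, "mlr"))
  expect_lte(full$rmsecv, 1.5 * mlr_rms)
})

test_that("method evaluation reports RMSECV and R2_CV with flags", {
  X <- matrix(seq_len(12), 12, 1) + 0
  y <- as.numeric(3 * X[, 1] - 1)
  ds <- suppressWarnings(etongue_dataset(X, y))
  r <- evaluate_method(ds, "mlr")
  expect_equal(r$RMSECV, 0, tolerance = 1e-8)
  expect_equal(r$R2_CV, 1, tolerance = 1e-8)

  set.seed(86)
  ds2 <- suppressWarnings(
    etongue_dataset(matrix(rnorm(24), 12, 2), rep(2, 12)))
  r2 <- evaluate_method(ds2, "mlr")
  expect_true(r2$degenerate_predictions)
  expect_equal(r2$R2_CV, 0)

  ds3 <- etongue_dataset(matrix(rnorm(30), 15, 2), rnorm(15))
  a <- evaluate_method(ds3, "rpls", list(k = 2, alpha = 0.75), seed = 5)
  b <- evaluate_method(ds3, "rpls", list(k = 2, alpha = 0.75), seed = 5)
  expect_identical(a, b)
})
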