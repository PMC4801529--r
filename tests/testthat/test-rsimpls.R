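# Robust PLS: classical limits, robustness, prediction identities,
# original-form equations, equivariance, serialization.

test_that("the classical path at full rank reproduces ordinary least squares", {
  d <- linear_map_data(n = 40, p = 5, noise_sd = 0.5, seed = 2)
  m_rpls <- rsimpls_fit(d$X, d$y, k = 5, alpha = 1)
  m_mlr <- mlr_fit(d$X, d$y)
  expect_lt(max(abs(m_rpls$coefficients - m_mlr$coefficients)), 1e-8)
  expect_lt(abs(m_rpls$intercept - m_mlr$intercept), 1e-8)
})

test_that("robust and classical coefficients agree closely on clean data", {
  rels <- vapply(1:5, function(s) {
    d <- linear_map_data(n = 100, p = 7, noise_sd = 0.1, seed = s)
    m_r <- rsimpls_fit(d$X, d$y, k = 7, alpha = 0.75, seed = s)
    m_c <- simpls_fit(d$X, d$y, k = 7)
    rel_l2(m_r$coefficients, m_c$coefficients)
  }, numeric(1))
  expect_lt(median(rels), 0.02)
})

test_that("bad leverage contamination barely moves the robust fit", {
  sim <- generate_dataset(synthetic_config(
    n_samples = 100, seed = 7,
    contamination = list(list(type = "bad_leverage", fraction = 0.15,
                              magnitude = 10))
  ))
  ds <- sim$dataset
  bt <- sim$truth$coefficients
  err_r <- sqrt(sum((rsimpls_fit(ds$X, ds$y, k = 7, alpha = 0.75,
                                 seed = 7)$coefficients - bt)^2))
  err_c <- sqrt(sum((simpls_fit(ds$X, ds$y, k = 7)$coefficients - bt)^2))
  expect_lt(err_r, 0.2 * err_c)
})

test_that("a single response outlier cannot drag the fit arbitrarily far", {
  d <- linear_map_data(n = 100, p = 7, noise_sd = 0.1, seed = 1)
  y3 <- d$y; y3[1] <- y3[1] + 1e3
  y6 <- d$y; y6[1] <- y6[1] + 1e6   # 1000x further out
  b3 <- rsimpls_fit(d$X, y3, k = 7, alpha = 0.75, seed = 1)$coefficients
  b6 <- rsimpls_fit(d$X, y6, k = 7, alpha = 0.75, seed = 1)$coefficients
  expect_lt(rel_l2(b6, b3), 1e-8)  # the outlier is rejected either way
})

test_that("predictions are linear in the stored coefficients", {
  d <- linear_map_data(n = 30, p = 4, noise_sd = 0.2, seed = 3)
  m <- rsimpls_fit(d$X, d$y, k = 3, alpha = 0.75, seed = 3)
  # round trip on the training matrix
  expect_equal(predict(m, d$X), m$fitted)
  expect_equal(d$y - predict(m, d$X), m$residuals)
  # equation form is algebraically identical
  eq <- equation_original_form(m)
  expect_lt(max(abs(evaluate_equation(eq, d$X) - predict(m, d$X))), 1e-10)
  expect_error(predict(m, d$X[, 1:3]), "columns")

  const <- structure(list(coefficients = rep(0, 4), intercept = 2.5),
                     class = "rpls_model")
  expect_equal(predict(const, d$X), rep(2.5, 30))
})

test_that("the original-form equation absorbs centering and column scaling", {
  d <- linear_map_data(n = 60, p = 5, noise_sd = 0.2, seed = 4)
  Xc <- scale(d$X, scale = FALSE)
  m <- rsimpls_fit(Xc, d$y, k = 5, alpha = 1)
  expect_equal(equation_original_form(m)$intercept, mean(d$y))

  # scaling one sensor by 10 divides its raw-unit coefficient by 10
  m0 <- rsimpls_fit(d$X, d$y, k = 5, alpha = 0.75, seed = 9)
  Xs <- d$X; Xs[, 2] <- Xs[, 2] * 10
  m1 <- rsimpls_fit(Xs, d$y, k = 5, alpha = 0.75, seed = 9)
  expect_equal(m1$coefficients[2], m0$coefficients[2] / 10, tolerance = 1e-6)
  expect_lt(max(abs(predict(m1, Xs) - predict(m0, d$X))), 1e-6)
})

test_that("full-rank fits are equivariant under shift and positive sensor scaling", {
  # at k = p the fitted hyperplane is scale-equivariant exactly; for
  # k < p no PLS variant is (column scaling changes the Krylov basis)
  d <- linear_map_data(n = 100, p = 7, noise_sd = 0.3, seed = 5)
  m0 <- rsimpls_fit(d$X, d$y, k = 7, alpha = 0.75, seed = 5)
  set.seed(55)
  shift <- runif(7, -5, 5); scl <- runif(7, 0.2, 50)
  Xt <- sweep(sweep(d$X, 2, scl, "*"), 2, shift, "+")
  m1 <- rsimpls_fit(Xt, d$y, k = 7, alpha = 0.75, seed = 5)
  expect_lt(max(abs(predict(m1, Xt) - predict(m0, d$X))), 1e-6)
})

test_that("serialized models reproduce predictions exactly", {
  d <- linear_map_data(n = 40, p = 6, noise_sd = 0.2, seed = 6)
  m <- rsimpls_fit(d$X, d$y, k = 4, alpha = 0.75, seed = 6)
  f <- tempfile(fileext = ".json")
  write_rpls_model(m, f)
  back <- read_rpls_model(f)
  expect_equal(predict(back, d$X), predict(m, d$X), tolerance = 1e-12)
  expect_equal(back$coefficients, unname(m$coefficients), tolerance = 1e-12)
})

test_that("invalid latent counts and degenerate responses are refused", {
  d <- linear_map_data(n = 20, p = 5, seed = 8)
  expect_error(rsimpls_fit(d$X, d$y, k = 6), "k must lie")
  expect_error(rsimpls_fit(d$X, rep(1, 20), k = 2), "degenerate response")
})
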