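# The synthetic e-tongue study generator.

test_that("contamination counts are exact and fractions are bounded", {
  sim <- generate_dataset(synthetic_config(
    n_samples = 50, seed = 1,
    contamination = list(list(type = "vertical", fraction = 0.2,
                              magnitude = 10))
  ))
  expect_length(sim$truth$outlier_ids, 10L)
  expect_true(all(sim$truth$outlier_types == "vertical"))

  expect_error(synthetic_config(contamination = list(
    list(type = "vertical", fraction = 0.3, magnitude = 5),
    list(type = "bad_leverage", fraction = 0.25, magnitude = 5)
  )), "below 0.5")
})

test_that("the noiseless limit is exactly linear with minimum-norm truth", {
  cfg <- synthetic_config(n_samples = 20, sensor_noise_sd = 0,
                          nuisance_sd = 0, response_noise_sd = 0, seed = 5)
  sim <- generate_dataset(cfg)
  eq_pred <- sim$truth$intercept +
    as.numeric(sim$dataset$X %*% sim$truth$coefficients)
  expect_lt(max(abs(sim$dataset$y - eq_pred)), 1e-10)
  l <- sim$truth$loadings
  expect_lt(max(abs(sim$truth$coefficients - l / sum(l^2))), 1e-10)

  # minimum-norm least squares (the rank-deficient analogue of MLR)
  skip_if_not_installed("MASS")
  Xc <- scale(sim$dataset$X, scale = FALSE)
  bmn <- as.numeric(MASS::ginv(Xc) %*% (sim$dataset$y - mean(sim$dataset$y)))
  expect_lt(max(abs(bmn - sim$truth$coefficients)), 1e-8)
})

test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_samples = 30, seed = 42,
                          contamination = study_contamination())
  s1 <- generate_dataset(cfg); s2 <- generate_dataset(cfg)
  expect_identical(s1$dataset$X, s2$dataset$X)
  expect_identical(s1$dataset$y, s2$dataset$y)
  expect_identical(s1$truth$outlier_ids, s2$truth$outlier_ids)
})

test_that("robust fits recover the generating coefficients on clean data", {
  rels <- vapply(1:10, function(s) {
    sim <- generate_dataset(synthetic_config(n_samples = 100, seed = s))
    m <- rsimpls_fit(sim$dataset$X, sim$dataset$y, k = 7, alpha = 0.75,
                     seed = s)
    rel_l2(m$coefficients, sim$truth$coefficients)
  }, numeric(1))
  expect_lt(median(rels), 0.10)
})

test_that("fitted equations live on the raw-sensor scale of real arrays", {
  sim <- generate_dataset(synthetic_config(seed = 2))
  m <- rsimpls_fit(sim$dataset$X, sim$dataset$y, k = 4, alpha = 0.75,
                   seed = 2)
  cf <- equation_original_form(m)$coefficients
  # coefficient magnitudes in the 1e-5..1e-2 band typical of raw
  # potentiometric units (baselines of order 10^3)
  expect_true(all(abs(cf) > 1e-6 & abs(cf) < 1e-1))
})

test_that("panel score draws respect the rank-scale bounds", {
  expect_equal(generate_panel_scores(2.4, 8, sd = 0, seed = 1),
               rep(2.4, 8))
  hi <- generate_panel_scores(5.4, 500, sd = 2, seed = 2)
  expect_true(all(hi <= 5.5 & hi >= 0.5))

  means <- vapply(1:200, function(s) {
    mean(generate_panel_scores(2.5, 10, sd = 0.5, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(means) - 2.5), 0.05)
})

test_that("replicate series stabilize before the averaging window", {
  flat <- generate_replicate_series(7, list(n_cycles = 7, drift = 0,
                                            stabilization = 3, noise_sd = 0))
  expect_equal(flat, rep(7, 7))

  drifted <- generate_replicate_series(7, list(n_cycles = 7, drift = 100,
                                               stabilization = 3,
                                               noise_sd = 0))
  expect_false(isTRUE(all.equal(drifted[1], 7)))
  expect_equal(average_replicates(drifted, 4), 7)
})

test_that("emitted CSVs round trip through the ingest modules byte-identically", {
  cfg <- synthetic_config(n_samples = 6, seed = 9,
                          replicate_plan = list(n_cycles = 7, drift = 30,
                                                stabilization = 3,
                                                noise_sd = 0.5))
  sim <- generate_dataset(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_csvs(sim, d1)
  write_synthetic_csvs(sim, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  suppressWarnings(ds <- read_dataset(file.path(d1, "features.csv"),
                                      file.path(d1, "response.csv")))
  expect_equal(unname(ds$X), unname(sim$dataset$X), tolerance = 1e-9)

  # replicate averaging of the emitted series reproduces the matrix when
  # the replicate noise is zero
  cfg0 <- synthetic_config(n_samples = 4, seed = 10)
  sim0 <- generate_dataset(cfg0)
  d0 <- tempfile()
  write_synthetic_csvs(sim0, d0)
  reps <- read.csv(file.path(d0, "replicates.csv"))
  X <- assemble_matrix(reps)
  expect_equal(unname(X), unname(sim0$dataset$X), tolerance = 1e-8)

  panel <- read_panel_scores(file.path(d0, "panel_scores.csv"))
  expect_length(panel, 4L)
})
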