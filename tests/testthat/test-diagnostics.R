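# Standardized residuals, score distances, cutoffs, outlier classes.

test_that("standardized residuals use the n - p - 1 scale", {
  r <- c(1, -1, 1, -1, 0)
  y <- rnorm(5); yhat <- y - r
  out <- standardized_residuals(y, yhat, p = 1)
  expect_equal(out$s, sqrt(4 / 3))
  expect_equal(out$s, 1.1547, tolerance = 1e-4)
  expect_equal(out$Sr, c(0.866, -0.866, 0.866, -0.866, 0), tolerance = 1e-3)

  perfect <- standardized_residuals(y, y, p = 1)
  expect_true(perfect$exact_fit)
  expect_equal(perfect$Sr, rep(0, 5))

  # doubling residuals doubles s, Sr unchanged
  out2 <- standardized_residuals(y, y - 2 * r, p = 1)
  expect_equal(out2$s, 2 * out$s)
  expect_equal(out2$Sr, out$Sr)

  expect_error(standardized_residuals(y[1:3], yhat[1:3], p = 2), "n > p")
})

test_that("score distances are rooted Mahalanobis distances", {
  expect_equal(score_distances(matrix(c(3, 4), 1), c(0, 0), diag(2)), 5)
  expect_equal(score_distances(matrix(c(1, 2), 1), c(1, 2), diag(2)), 0)
  expect_equal(score_distances(matrix(3, 1), 1, matrix(4)), 1)
  expect_error(score_distances(matrix(1:4, 2), c(0, 0),
                               matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("the SD cutoff is the rooted 0.975 chi-square quantile", {
  expect_equal(sd_cutoff(2), sqrt(qchisq(0.975, 2)))
  expect_equal(sd_cutoff(2), 2.7162, tolerance = 1e-4)
  expect_equal(sd_cutoff(1), 2.2414, tolerance = 1e-4)
  expect_true(all(diff(sd_cutoff(1:10)) > 0))
})

test_that("the three outlier classes partition the (Sr, SD) plane", {
  cut <- sd_cutoff(2)
  d <- classify_samples(Sr = c(0.1, 4, 4, 0.3),
                        SD = c(10 * cut, 10 * cut, 0, 0.5),
                        sd_cutoff = cut)
  expect_equal(d$map$label,
               c("good_leverage", "bad_leverage", "vertical", "regular"))

  # exhaustive and mutually exclusive over a random grid
  set.seed(71)
  sr <- rnorm(200, sd = 3); sd_ <- abs(rnorm(200, sd = 3))
  lab <- classify_samples(sr, sd_, sd_cutoff = cut)$map$label
  expect_true(all(lab %in% c("regular", "good_leverage", "bad_leverage",
                             "vertical")))
  recomputed <- ifelse(sd_ > cut & abs(sr) > 2.5, "bad_leverage",
                ifelse(sd_ > cut, "good_leverage",
                ifelse(abs(sr) > 2.5, "vertical", "regular")))
  expect_identical(lab, recomputed)
})

test_that("clean-data flag rates stay near their nominal levels", {
  for (s in 1:2) {
    sim <- generate_dataset(synthetic_config(n_samples = 500, seed = 100 + s))
    ds <- sim$dataset
    m <- rsimpls_fit(ds$X, ds$y, k = 4, alpha = 0.75, seed = s)
    d <- diagnose(m, ds)
    sd_rate <- mean(d$map$SD > d$sd_cutoff)
    sr_rate <- mean(abs(d$map$Sr) > d$sr_cutoff)
    expect_gte(sd_rate, 0.005); expect_lte(sd_rate, 0.08)
    expect_gte(sr_rate, 0.002); expect_lte(sr_rate, 0.05)
  }
})

test_that("planted outliers are detected with high sensitivity", {
  for (s in 1:2) {
    sim <- generate_dataset(synthetic_config(
      n_samples = 200, seed = 200 + s,
      contamination = list(
        list(type = "vertical", fraction = 0.05, magnitude = 10),
        list(type = "bad_leverage", fraction = 0.05, magnitude = 10)
      )
    ))
    ds <- sim$dataset
    m <- rsimpls_fit(ds$X, ds$y, k = 4, alpha = 0.75, seed = s)
    d <- diagnose(m, ds)
    flagged <- d$map$id[d$map$label %in% c("vertical", "bad_leverage")]
    expect_gte(mean(sim$truth$outlier_ids %in% flagged), 0.9)
  }
})

test_that("the exclusion policy keeps good leverage and honors overrides", {
  cut <- sd_cutoff(2)
  d <- classify_samples(Sr = c(0.1, 4, 4, 0.3),
                        SD = c(10 * cut, 10 * cut, 0, 0.5),
                        sd_cutoff = cut, ids = c("a", "b", "c", "d"))
  expect_setequal(excluded_ids(d), c("b", "c"))
  expect_setequal(excluded_ids(d, manual_exclude = "d"), c("b", "c", "d"))
  expect_setequal(excluded_ids(d, manual_include = "c"), "b")
})

test_that("the outlier map exports to CSV with its cutoffs", {
  d <- classify_samples(Sr = c(0, 3), SD = c(0, 1), sd_cutoff = 2)
  f <- tempfile(fileext = ".csv")
  write_outlier_map(d, f)
  back <- read.csv(f)
  expect_equal(back$label, c("regular", "vertical"))
  expect_equal(back$sd_cutoff, c(2, 2))
})
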