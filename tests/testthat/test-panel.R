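# Grubbs screening, panel summaries and the five-rank scale.

test_that("Grubbs screen removes a gross outlier and leaves clean data alone", {
  # oracle: direct formula.  x = c(8, 9, 10, 11, 50): G = |50 - 17.6| / sd
  x <- c(8, 9, 10, 11, 50)
  G_hand <- max(abs(x - mean(x))) / sd(x)
  expect_equal(G_hand, 1.7855, tolerance = 1e-4)
  # published two-sided critical value for N = 5, alpha = 0.05 is 1.715
  expect_equal(grubbs_critical(5, 0.05), 1.715, tolerance = 1e-3)

  scr <- grubbs_screen(x, alpha = 0.05)
  expect_equal(scr$cleaned, c(8, 9, 10, 11))
  expect_equal(scr$removed$index, 5L)
  expect_equal(scr$removed$G, G_hand)

  clean <- grubbs_screen(c(8, 9, 10, 11, 12), alpha = 0.05)
  expect_equal(clean$cleaned, c(8, 9, 10, 11, 12))
  expect_equal(nrow(clean$removed), 0L)
})

test_that("degenerate panels are refused or passed through", {
  expect_error(grubbs_screen(c(1, 2)), "at least 3")
  expect_error(grubbs_screen(1:5, alpha = 0.7), "alpha")
  # zero variance: G undefined, vector returned unchanged
  same <- grubbs_screen(c(3, 3, 3, 3))
  expect_equal(same$cleaned, c(3, 3, 3, 3))
  expect_equal(nrow(same$removed), 0L)
})

test_that("Grubbs screening is idempotent and never drops below 3 scores", {
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(sample(4:12, 1))
    if (i %% 2 == 0) x[1] <- x[1] + sample(c(-1, 1), 1) * runif(1, 3, 30)
    scr <- grubbs_screen(x)
    expect_gte(length(scr$cleaned), 3)
    rescr <- grubbs_screen(scr$cleaned)
    expect_equal(rescr$cleaned, scr$cleaned)
    expect_equal(nrow(rescr$removed), 0L)
  }
})

test_that("panel summaries give mean and n-1 sd, flagging single scores", {
  rec <- summarize_panel(c(1, 2, 3), sample_id = "a")
  expect_equal(rec$mean_intensity, 2)
  expect_equal(rec$sd_intensity, 1)
  expect_equal(rec$n_assessors, 3L)

  # hand value: mean 0.7, sd = sqrt(0.1 / 3)
  rec2 <- summarize_panel(c(0.5, 0.6, 0.9, 0.8))
  expect_equal(rec2$mean_intensity, 0.7)
  expect_equal(rec2$sd_intensity, sqrt(0.1 / 3))
  expect_equal(rec2$sd_intensity, 0.1826, tolerance = 1e-3)

  expect_warning(rec3 <- summarize_panel(4.78), "single")
  expect_equal(rec3$mean_intensity, 4.78)
  expect_equal(rec3$sd_intensity, 0)
  expect_true(rec3$degenerate)
})

test_that("intensities map to the five ranks with a closed top interval", {
  expect_equal(rank_from_intensity(0.63), "I")
  expect_equal(rank_from_intensity(3.01), "III")
  expect_equal(rank_from_intensity(4.78), "V")
  # boundaries: half-open below, closed at the very top
  expect_equal(rank_from_intensity(c(1.5, 2.5, 4.5, 5.5)),
               c("II", "III", "V", "V"))
  expect_error(rank_from_intensity(5.6), "off the rank scale")
  expect_error(rank_from_intensity(0.4), "off the rank scale")
})

test_that("rank mapping is monotone in intensity", {
  grid <- seq(0.5, 5.5, by = 0.01)
  ranks <- match(rank_from_intensity(grid), c("I", "II", "III", "IV", "V"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("panel CSV round trip screens and summarizes per sample", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(
    sample_id = rep(c("s1", "s2"), c(5, 4)),
    assessor_id = c(1:5, 1:4),
    score = c(2, 2.2, 1.8, 2.1, 5.4, 1, 1.1, 0.9, 1)
  )
  write.csv(df, f, row.names = FALSE)
  sets <- read_panel_scores(f)
  expect_named(sets, c("s1", "s2"))
  recs <- screen_panel(sets)
  expect_equal(recs$sample_id, c("s1", "s2"))
  # the 5.4 score is screened out before averaging
  expect_equal(recs$n_assessors, c(4L, 4L))
  expect_equal(recs$mean_intensity[1], mean(c(2, 2.2, 1.8, 2.1)))
  removed <- attr(recs, "removed")
  expect_equal(removed$s1$value, 5.4)

  out <- tempfile(fileext = ".csv")
  write_panel_records(recs, out)
  back <- read.csv(out)
  expect_equal(back$mean_intensity, recs$mean_intensity, tolerance = 1e-8)
})
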