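test_that("moving ranges are the absolute successive differences", {
  expect_equal(moving_ranges(c(3, 3, 3, 3)), c(0, 0, 0))
  expect_equal(moving_ranges(c(1, 4, 2)), c(3, 2))
  expect_equal(moving_ranges(5), numeric(0))
  expect_equal(moving_ranges(numeric(0)), numeric(0))
  set.seed(1)
  x <- sample(1:7, 50, replace = TRUE)
  expect_equal(moving_ranges(x), oracle_chart(x)$mr)
  # translation invariance
  expect_equal(moving_ranges(x + 3), moving_ranges(x))
})

test_that("sigma estimation follows mean moving range over d2", {
  expect_equal(estimate_sigma(c(0, 0, 0)), 0)
  expect_equal(estimate_sigma(c(3, 2)), 2.5 / 1.128)
  expect_error(estimate_sigma(numeric(0)), "insufficient")
})

test_that("the d2 constant equals the expected standard-normal pair range", {
  # E|X1 - X2| for iid standard normals is 2/sqrt(pi)
  expect_equal(round(2 / sqrt(pi), 3), shewhart_d2())
  expect_equal(shewhart_d2(), 1.128)
})

test_that("chart fitting reproduces the hand-computed example", {
  rec <- make_records(c(2, 5, 3, 6, 2, 5, 3))
  ch <- fit_chart(rec, "stress", L = 2)
  expect_equal(ch$phase1_mean, mean(c(2, 5, 3, 6, 2, 5, 3)))
  expect_equal(ch$mr_mean, mean(c(3, 2, 3, 4, 3, 2)))
  expect_equal(ch$sigma_hat, 2.51182, tolerance = 1e-5)
  expect_equal(ch$ucl, 8.73793, tolerance = 1e-5)
  ch3 <- fit_chart(rec, "stress", L = 3)
  expect_equal(ch3$ucl - ch$ucl, ch$sigma_hat, tolerance = 1e-12)
})

test_that("a zero-variability baseline collapses the limit onto the mean", {
  rec <- make_records(rep(4, 8))
  ch <- fit_chart(rec, "stress", L = 2)
  expect_equal(ch$phase1_mean, 4)
  expect_equal(ch$sigma_hat, 0)
  expect_equal(ch$ucl, 4)
  expect_false(exceeds_ucl(ch, 4))
  expect_true(exceeds_ucl(ch, 5))
})

test_that("chart fitting needs at least two completed baseline observations", {
  expect_error(fit_chart(make_records(4), "stress"), "insufficient")
  rec <- make_records(c(4, 5), completed = c(TRUE, FALSE))
  expect_error(fit_chart(rec, "stress"), "insufficient")
})

test_that("exceedance is strict at the limit", {
  ch <- shewhart_chart(center = 3, sigma = 1, L = 2)
  expect_equal(ch$ucl, 5)
  expect_false(exceeds_ucl(ch, 5))
  expect_true(exceeds_ucl(ch, 5 + 1e-9))
  expect_equal(exceeds_ucl(ch, c(4, 5, 6)), c(FALSE, FALSE, TRUE))
})

test_that("the growing window uses only observations up to as_of, then freezes", {
  vals <- c(2, 5, 3, 6, 2, 5, 3, 4, 7, 1)
  rec <- make_records(vals, days = rep(1:10, each = 1), slots = rep(1, 10))
  early <- fit_chart(rec, "stress", baseline_end_day = 7, as_of = c(4, 1))
  expect_equal(early$n_baseline, 4)
  expect_equal(early$phase1_mean, mean(vals[1:4]))
  expect_false(early$frozen)
  frozen <- fit_chart(rec, "stress", baseline_end_day = 7, as_of = c(9, 1))
  expect_equal(frozen$n_baseline, 7)
  expect_equal(frozen$phase1_mean, mean(vals[1:7]))
  expect_true(frozen$frozen)
  # days past the baseline window never enter the fit
  full <- fit_chart(rec, "stress", baseline_end_day = 7)
  expect_equal(full$phase1_mean, frozen$phase1_mean)
})

test_that("translation and scale act on the chart as they must", {
  set.seed(7)
  for (i in 1:50) {
    x <- stats::runif(sample(5:30, 1), 1, 7)
    rec <- make_records(round(x), days = seq_along(x), slots = rep(1, length(x)))
    rec$stress <- x  # use continuous values for exact arithmetic
    ch <- fit_chart(rec, "stress", baseline_end_day = length(x))
    c_shift <- 2.5
    rec2 <- rec; rec2$stress <- x + c_shift
    ch2 <- fit_chart(rec2, "stress", baseline_end_day = length(x))
    expect_equal(ch2$phase1_mean, ch$phase1_mean + c_shift, tolerance = 1e-12)
    expect_equal(ch2$ucl, ch$ucl + c_shift, tolerance = 1e-12)
    expect_equal(ch2$sigma_hat, ch$sigma_hat, tolerance = 1e-12)
    k <- 1.7
    rec3 <- rec; rec3$stress <- x * k
    ch3 <- fit_chart(rec3, "stress", baseline_end_day = length(x))
    expect_equal(ch3$sigma_hat, k * ch$sigma_hat, tolerance = 1e-12)
    expect_equal(ch3$ucl - ch3$phase1_mean, k * (ch$ucl - ch$phase1_mean),
                 tolerance = 1e-12)
  }
})

test_that("fit_charts audits every person-variable pair", {
  records <- generate_cohort(3, seed = 2) |> simulate_ema(seed = 2)
  charts <- fit_charts(records)
  expect_equal(nrow(charts), 12)
  expect_true(all(charts$ucl >= charts$phase1_mean, na.rm = TRUE))
  # UCL recomputable from stored components
  expect_equal(charts$ucl,
               charts$phase1_mean + charts$L * charts$sigma_hat,
               tolerance = 1e-12)
  expect_equal(charts$sigma_hat, charts$mr_mean / shewhart_d2(),
               tolerance = 1e-12)
})
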