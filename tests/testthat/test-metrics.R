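test_that("relative deviation and its propagated SD", {
  expect_identical(relative_deviation(1, 1), 0)
  expect_equal(relative_deviation(1.1, 1.0), 0.10)
  expect_equal(relative_deviation(0.8, 1.0), -0.20)
  expect_error(relative_deviation(1, 0), "positive")
  expect_error(relative_deviation(1, -2), "positive")

  expect_identical(rd_sd(1, 0, 1, 0), 0)
  expect_equal(rd_sd(1, 0.1, 1, 0), 0.1)
  expect_equal(rd_sd(1, 0.1, 1, 0.1), 0.14142135623731, tolerance = 1e-10)
  expect_error(rd_sd(1, -0.1, 1, 0), "non-negative")
})

test_that("RMSE reduces to the root mean square of the deviations", {
  expect_equal(rmse(c(0.10, -0.10, 0.00)), 0.0816496580927726,
               tolerance = 1e-12)
  expect_equal(rmse(rep(-0.07, 5)), 0.07)
  expect_identical(rmse(0), 0)
  expect_error(rmse(numeric(0)), "non-empty")

  set.seed(601)
  for (i in 1:20) {
    rd <- stats::rnorm(stats::rpois(1, 10) + 1, 0, 0.2)
    expect_equal(rmse(rd), sqrt(mean(rd^2)), tolerance = 1e-14)
    expect_gte(rmse(rd) + 1e-14, abs(mean(rd)))
    n <- length(rd)
    expect_gte(rmse(rd) + 1e-14, sqrt(mean((rd - mean(rd))^2)))
  }
  # N-1 variant for sensitivity analysis
  rd <- c(0.1, -0.1, 0)
  expect_equal(rmse(rd, denominator = "n-1"),
               sqrt(stats::var(rd) + mean(rd)^2), tolerance = 1e-14)
})

test_that("MAPE is the mean absolute deviation in percent", {
  expect_equal(mape(c(0.10, -0.10, 0.00)), 6.66666666666667,
               tolerance = 1e-12)
  expect_identical(mape(c(0, 0, 0)), 0)
  expect_equal(mape(0.05), 5)
  expect_error(mape(numeric(0)), "non-empty")

  # bounded by the largest deviation; bounds the mean when signs agree
  set.seed(602)
  for (i in 1:10) {
    rd <- abs(stats::rnorm(8, 0.1, 0.05))
    expect_lte(mape(rd), 100 * max(abs(rd)) + 1e-12)
    expect_gte(mape(rd) + 1e-12, 100 * abs(mean(rd)))
  }
})

test_that("propagated RMSE SD matches a Monte-Carlo oracle", {
  expect_identical(rmse_sd(c(0.1, -0.2), c(0, 0)), 0)
  expect_equal(rmse_sd(0.1, 0.02), 0.02, tolerance = 1e-12)

  rd <- c(0.1, -0.1)
  sds <- c(0.02, 0.02)
  set.seed(603)
  draws <- replicate(1e5, {
    r <- rd + stats::rnorm(2, 0, sds)
    sqrt(mean(r^2))
  })
  expect_equal(rmse_sd(rd, sds), stats::sd(draws), tolerance = 0.05)
  expect_warning(rmse_sd(c(0, 0), c(0.1, 0.1)), "limiting")
})

test_that("propagated MAPE SD follows the quadrature rule", {
  expect_identical(mape_sd(c(0.1, 0.2), c(0, 0)), 0)
  expect_equal(mape_sd(0.1, 0.05), 5)
  expect_equal(mape_sd(rep(0.05, 4), rep(0.1, 4)), 100 / 4 * sqrt(0.04),
               tolerance = 1e-12)
})

test_that("threshold counts use strict absolute-value exceedance", {
  tc <- threshold_counts(c(0.05, 0.15, -0.25))
  expect_identical(tc$count, c(2L, 1L))
  expect_identical(threshold_counts(0.10)$count, c(0L, 0L))
  rd <- c(0.25, -0.3, 0.21)
  expect_identical(threshold_counts(rd)$count, c(3L, 3L))

  set.seed(604)
  for (i in 1:10) {
    rd <- stats::rnorm(20, 0, 0.15)
    tc <- threshold_counts(rd)
    expect_lte(tc$count[2], tc$count[1])
    expect_lte(tc$count[1], length(rd))
  }
})

test_that("CV and its cohort summary", {
  expect_equal(cv(2.0, 0.1), 0.05)
  expect_identical(cv(1.5, 0), 0)
  expect_error(cv(0, 0.1), "positive")
  s <- cv_summary(c(0.04, 0.05, 0.06))
  expect_equal(s$mean, 0.05)
  expect_equal(s$median, 0.05)
  expect_equal(s$min, 0.04)
  expect_equal(s$max, 0.06)
})

test_that("regression of estimated on reference TIAs matches normal equations", {
  r <- suppressWarnings(ols_slope_test(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_lt(r$p_slope, 1e-10)
  expect_equal(suppressWarnings(
    ols_slope_test(2 * c(1, 2, 3, 5), c(1, 2, 3, 5)))$slope, 2,
    tolerance = 1e-12)

  set.seed(605)
  x <- stats::runif(20, 1, 4)
  y <- 0.5 + 0.9 * x + stats::rnorm(20, 0, 0.2)
  r <- ols_slope_test(y, x)
  # closed-form normal equations and t-test
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  se_b <- sqrt(sum(res^2) / (length(x) - 2) / sxx)
  p <- 2 * stats::pt(-abs(b / se_b), length(x) - 2)
  expect_equal(r$slope, b, tolerance = 1e-10)
  expect_equal(r$intercept, a, tolerance = 1e-10)
  expect_equal(r$p_slope, p, tolerance = 1e-10)

  expect_error(ols_slope_test(c(1, 2, 3), c(2, 2, 2)), "degenerate")
  expect_error(ols_slope_test(1:2, 1:2), "length >= 3")
})

test_that("accuracy report assembles consistent summaries", {
  set.seed(606)
  rtia <- stats::runif(12, 1.5, 3)
  etia <- rtia * (1 + stats::rnorm(12, 0, 0.1))
  rep1 <- accuracy_report(etia, rep(0.05, 12), rtia, rep(0.04, 12), "TPX")
  rd <- (etia - rtia) / rtia
  expect_equal(rep1$rmse, sqrt(mean(rd^2)), tolerance = 1e-12)
  expect_equal(rep1$mape, 100 * mean(abs(rd)), tolerance = 1e-12)
  expect_lte(rep1$rd20, rep1$rd10)
  expect_lte(rep1$rd10, rep1$n)
  expect_equal(rep1$rd_median, stats::median(rd), tolerance = 1e-12)
  # NA uncertainties are treated as absent (zero)
  rep2 <- accuracy_report(etia, rep(NA_real_, 12), rtia, rep(NA_real_, 12))
  expect_identical(rep2$rmse_sd, 0)
  expect_identical(rep2$mape_sd, 0)
})
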