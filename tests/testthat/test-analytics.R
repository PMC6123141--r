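# DVH bands, endpoint tables, time series, tests, correlations, regressions.

step_dvh <- function(dose_gy, vol = 10) {
  b <- as.integer(dose_gy * 100)
  dvh_from_diff({ x <- numeric(b); x[b] <- vol; x }, bin_width = 0.01)
}

test_that("band aggregation degenerates correctly and matches percentiles", {
  d <- step_dvh(60)
  bands <- aggregate_dvhs(rep(list(d), 5))
  expect_equal(bands$mean, bands$median)
  expect_equal(bands$q1, bands$q3)
  expect_equal(bands$mean, c(d$cumulative, 0))

  # two uniform-dose curves of equal volume, relative mode
  rel <- aggregate_dvhs(list(step_dvh(50), step_dvh(70)), relative = TRUE)
  i40 <- which.min(abs(rel$dose - 40))
  i60 <- which.min(abs(rel$dose - 60))
  expect_equal(rel$mean[i40], 100)
  expect_equal(rel$mean[i60], 50)
  expect_equal(rel$mean[length(rel$mean)], 0)

  # random sample: per-bin values equal a direct percentile oracle
  set.seed(42)
  dvhs <- lapply(1:20, function(i) step_dvh(runif(1, 30, 70), runif(1, 5, 20)))
  b <- aggregate_dvhs(dvhs, percentiles = c(25, 75))
  n <- length(b$dose)
  curves <- vapply(dvhs, function(d)
    c(d$cumulative, rep(0, n - length(d$cumulative))), numeric(n))
  for (i in c(1, 1500, 4000, n)) {
    expect_equal(b$mean[i], mean(curves[i, ]))
    expect_equal(b$median[i], median(curves[i, ]))
    expect_equal(unname(b$q1[i]), unname(quantile(curves[i, ], 0.25)))
  }
  expect_true(all(diff(b$mean) <= 1e-12))
  expect_true(all(b$q1 <= b$median + 1e-12 & b$median <= b$q3 + 1e-12))
  expect_error(aggregate_dvhs(list()), "empty")
})

test_that("endpoint tables compose dvh_core calls and cap at eight specs", {
  dvhs <- list(a = step_dvh(60), b = step_dvh(50))
  specs <- parse_endpoint(c("D95%", "V20Gy"))
  tab <- endpoint_table(dvhs, specs)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("D_95%", "V_20Gy") %in% names(tab)))
  expect_equal(tab[["D_95%"]],
               vapply(dvhs, dose_at_volume, 0, spec = specs[[1]]),
               ignore_attr = TRUE)
  nine <- parse_endpoint(rep("D95%", 9))
  expect_error(endpoint_table(dvhs, nine), "at most 8")
})

test_that("moving average respects the distinct-date look-back window", {
  dates <- as.Date("2024-01-01") + 0:9
  ts <- time_series(dates, 1:10, lookback_window = 3)
  expect_equal(ts$moving_average[10], mean(c(8, 9, 10)))
  expect_equal(ts$moving_average[1], 1)
  # window >= span equals the running cumulative mean
  ts_all <- time_series(dates, 1:10, lookback_window = 10)
  expect_equal(ts_all$moving_average, vapply(1:10, function(i)
    mean(1:i), 0))

  # constant series: flat average, collapsed band
  tc <- time_series(dates, rep(4, 10), lookback_window = 5)
  expect_true(all(tc$moving_average == 4))
  expect_equal(tc$band_low, 4)
  expect_equal(tc$band_high, 4)
  expect_equal(tc$sample_mean, 4)

  # excluding a gross outlier removes it from the moving average
  vals <- c(1, 1, 1, 100, 1, 1, 1, 1, 1, 1)
  t_ex <- time_series(dates, vals, lookback_window = 4, excluded = 4L)
  expect_equal(t_ex$moving_average[6], 1)
  expect_equal(t_ex$sample_mean, 1)
  t_in <- time_series(dates, vals, lookback_window = 4)
  expect_gt(t_in$moving_average[6], 1)
  # repeated dates count once toward the window
  dd <- as.Date(c("2024-01-01", "2024-01-01", "2024-01-02", "2024-01-03"))
  td <- time_series(dd, c(2, 4, 6, 8), lookback_window = 2)
  expect_equal(td$moving_average[4], mean(c(6, 8)))
  expect_error(time_series(dates, 1:10, excluded = 1:10), "no data")
})

test_that("group comparisons: identity, separation, exact rank-sum", {
  g <- c(1.2, 2.5, 3.1, 4.8, 5.0)
  same <- compare_groups(g, g)
  expect_equal(same$p_ttest, 1)
  expect_true(same$p_wilcoxon > 0.99)

  set.seed(7)
  a <- rnorm(50); b <- rnorm(50, mean = 5)
  sep <- compare_groups(a, b)
  expect_lt(sep$p_ttest, 1e-10)
  expect_lt(sep$p_wilcoxon, 1e-10)
  expect_true(sep$p_normality_g1 > 0.01)

  # exact enumeration oracle for small untied samples
  set.seed(11)
  for (i in 1:5) {
    g1 <- round(rnorm(5), 3); g2 <- round(rnorm(5, 0.8), 3)
    if (anyDuplicated(c(g1, g2))) next
    res <- compare_groups(g1, g2)
    expect_equal(res$p_wilcoxon, oracle_ranksum_p(g1, g2),
                 tolerance = 1e-12)
  }

  # symmetry under group exchange
  r1 <- compare_groups(a, b); r2 <- compare_groups(b, a)
  expect_equal(r1$p_ttest, r2$p_ttest)
  expect_equal(r1$p_wilcoxon, r2$p_wilcoxon)

  const <- compare_groups(rep(2, 5), rep(2, 6))
  expect_true(is.na(const$p_normality_g1))
  expect_equal(const$p_ttest, 1)
})

test_that("correlation matrix: exact lines, nulls, missing handling", {
  x <- seq(-3, 3, length.out = 40)
  df <- data.frame(x = x, up = x, down = -2 * x + 3)
  cm <- correlation_matrix(df)
  expect_equal(unname(cm$r["x", "up"]), 1)
  expect_equal(unname(cm$r["x", "down"]), -1)
  expect_equal(diag(cm$r), c(x = 1, up = 1, down = 1))
  expect_true(isSymmetric(cm$r))

  set.seed(3)
  dn <- data.frame(a = rnorm(1000), b = rnorm(1000))
  cmn <- correlation_matrix(dn)
  expect_lt(abs(cmn$r["a", "b"]), 0.1)
  expect_gt(cmn$p["a", "b"], 1e-4)

  # pairwise-complete deletion; pairs under 3 cases are NA
  dm <- data.frame(a = c(1, 2, 3, NA, NA), b = c(2, 4, 6, 8, 10),
                   c = c(1, NA, NA, NA, 2))
  cmm <- correlation_matrix(dm)
  expect_equal(unname(cmm$n["a", "b"]), 3)
  expect_true(is.na(cmm$r["a", "c"]))
})

test_that("univariable regression recovers exact and noisy lines", {
  x <- seq(0, 10, length.out = 50)
  fit <- suppressWarnings(fit_univariable(x, 2 * x + 1))  # exact fit
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n, 50)

  set.seed(12)
  xs <- runif(200, 0, 5)
  ys <- 2 * xs + 1 + rnorm(200, sd = 0.1)
  f2 <- fit_univariable(xs, ys)
  expect_lt(abs(f2$slope - 2), 3 * f2$std_err)
  expect_lt(f2$p_value, 1e-10)

  # slope * sd(x)/sd(y) equals Pearson R
  cm <- correlation_matrix(data.frame(x = xs, y = ys))
  expect_equal(f2$slope * sd(xs) / sd(ys), unname(cm$r["x", "y"]),
               tolerance = 1e-9)

  expect_error(fit_univariable(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(fit_univariable(rep(1, 10), rnorm(10)), "constant")
})

test_that("multivariable regression recovers planes and flags collinearity", {
  set.seed(9)
  x1 <- runif(60); x2 <- runif(60)
  exact <- suppressWarnings(fit_multivariable(data.frame(x1 = x1, x2 = x2),
                                              2 * x1 - 3 * x2 + 5))
  expect_equal(unname(exact$coefficients), c(2, -3), tolerance = 1e-9)
  expect_equal(exact$intercept, 5, tolerance = 1e-9)
  expect_equal(exact$r_squared, 1, tolerance = 1e-9)

  y <- 2 * x1 - 3 * x2 + 5 + rnorm(60, sd = 0.2)
  noisy <- fit_multivariable(data.frame(x1 = x1, x2 = x2), y)
  expect_lt(noisy$f_prob, 1e-10)
  expect_true(all(noisy$p_values < 0.01))

  expect_error(fit_multivariable(data.frame(a = x1, b = 2 * x1), y),
               "collinear")
  expect_error(fit_multivariable(data.frame(a = x1[1:3], b = x2[1:3]),
                                 y[1:3]), "n > k")

  # single-predictor multivariable reproduces the univariable fit
  m1 <- fit_multivariable(data.frame(x = x1), y)
  u1 <- fit_univariable(x1, y)
  expect_equal(unname(m1$coefficients), u1$slope, tolerance = 1e-9)
  expect_equal(m1$intercept, u1$intercept, tolerance = 1e-9)
  expect_equal(m1$r_squared, u1$r_squared, tolerance = 1e-9)
  expect_equal(unname(m1$p_values), u1$p_value, tolerance = 1e-9)
})
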