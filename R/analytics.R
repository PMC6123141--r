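# Front-end analytics: DVH band aggregation, endpoint tables, time series
# with moving averages, two-group tests, correlation matrices, regressions.

MAX_ENDPOINTS <- 8L

#' Aggregate a sample of DVHs into mean/median/IQR bands
#'
#' Curves are resampled onto a common dose axis (0 to the largest maximum
#' dose in the sample, at the common bin width), padding beyond each
#' curve's own maximum with zero volume; the mean, median and the requested
#' percentiles are then taken per dose bin across the sample. In relative
#' mode each curve is first divided by its own structure volume (so curves
#' start at 100%).
#'
#' @param dvhs list of `dvh` objects sharing one bin width.
#' @param percentiles length-2 percentile bounds, default `c(25, 75)`.
#' @param relative express volumes as % of each structure's own volume.
#' @return object of class `dvh_bands`: `dose` (bin-edge axis, Gy) and
#'   per-bin `mean`, `median`, `q1`, `q3`.
#' @export
aggregate_dvhs <- function(dvhs, percentiles = c(25, 75), relative = FALSE) {
  if (!length(dvhs)) stop("empty DVH sample")
  stopifnot(all(vapply(dvhs, inherits, TRUE, "dvh")))
  bw <- unique(vapply(dvhs, `[[`, 0, "bin_width"))
  if (length(bw) != 1L)
    stop("DVHs must share one bin width; got: ", paste(bw, collapse = ", "))
  n <- max(vapply(dvhs, function(d) length(d$cumulative), 0L)) + 1L
  curves <- vapply(dvhs, function(d) {
    v <- c(d$cumulative, 0, rep(0, n - length(d$cumulative) - 1L))
    if (relative) v <- 100 * v / d$volume
    v
  }, numeric(n))
  curves <- matrix(curves, nrow = n)
  qs <- apply(curves, 1, stats::quantile,
              probs = sort(percentiles) / 100, names = FALSE)
  structure(list(dose = (seq_len(n) - 1L) * bw,
                 mean = rowMeans(curves),
                 median = apply(curves, 1, stats::median),
                 q1 = qs[1, ],
                 q3 = qs[2, ],
                 relative = relative,
                 n = length(dvhs)),
            class = "dvh_bands")
}

#' Endpoint table for a DVH sample
#'
#' Evaluates up to eight D/V endpoint specs on each DVH and returns one row
#' per ROI with the sample context columns (MRN, ROI names, prescription
#' dose, volume, dose summaries, minimum PTV distance, PTV overlap) followed
#' by one column per endpoint.
#'
#' @param dvhs list of `dvh` objects.
#' @param specs list of [endpoint_spec()] (at most 8).
#' @param meta optional data.frame (one row per DVH) of context columns.
#' @return data.frame.
#' @export
endpoint_table <- function(dvhs, specs, meta = NULL) {
  if (length(specs) > MAX_ENDPOINTS)
    stop("at most ", MAX_ENDPOINTS, " endpoints per query")
  stopifnot(all(vapply(specs, inherits, TRUE, "endpoint_spec")))
  base <- if (!is.null(meta)) {
    stopifnot(nrow(meta) == length(dvhs))
    meta
  } else {
    data.frame(roi = names(dvhs) %||% sprintf("roi%d", seq_along(dvhs)),
               stringsAsFactors = FALSE)
  }
  vals <- lapply(specs, function(sp)
    vapply(dvhs, function(d)
      tryCatch(evaluate_endpoint(d, sp), error = function(e) NA_real_), 0))
  names(vals) <- vapply(specs, endpoint_label, "")
  cbind(base, as.data.frame(vals, check.names = FALSE))
}

#' Time series with look-back moving average
#'
#' The moving average at each point is the mean of all non-excluded values
#' whose date falls within the look-back window ending at the point's date,
#' the window being counted in distinct simulation dates (a window of 6
#' covers the point's date and the five distinct dates before it). The
#' percentile band and the sample mean are computed over all non-excluded
#' values.
#'
#' @param dates Date vector (simulation dates).
#' @param values numeric vector.
#' @param lookback_window number of distinct dates in the window (>= 1).
#' @param bounds length-2 percentile bounds for the band, default `c(5, 95)`.
#' @param excluded integer indices excluded from the moving average, band
#'   and sample mean (they remain in the returned series).
#' @return object of class `time_series_result`.
#' @export
time_series <- function(dates, values, lookback_window = 6L,
                        bounds = c(5, 95), excluded = integer(0)) {
  stopifnot(length(dates) == length(values), lookback_window >= 1L)
  dates <- as.Date(dates)
  keep <- setdiff(seq_along(values), excluded)
  if (!length(keep)) stop("no data left after exclusion")
  ord <- order(dates)
  dates <- dates[ord]; values <- values[ord]
  keep <- match(keep, ord)
  excluded_sorted <- setdiff(seq_along(values), keep)
  udates <- sort(unique(dates[keep]))
  ma <- rep(NA_real_, length(values))
  for (i in seq_along(values)) {
    prior <- udates[udates <= dates[i]]
    if (!length(prior)) next
    win <- utils::tail(prior, lookback_window)
    sel <- keep[dates[keep] %in% win]
    if (length(sel)) ma[i] <- mean(values[sel])
  }
  qs <- stats::quantile(values[keep], probs = sort(bounds) / 100,
                        names = FALSE)
  structure(list(dates = dates, values = values, moving_average = ma,
                 band_low = qs[1], band_high = qs[2],
                 sample_mean = mean(values[keep]),
                 excluded = excluded_sorted),
            class = "time_series_result")
}

#' Two-group comparison
#'
#' Welch two-sample t test, Wilcoxon rank-sum test (exact when both groups
#' have at most 8 untied observations, normal approximation with continuity
#' and tie correction otherwise), and a Shapiro-Wilk normality p-value per
#' group (NA for constant groups, where the test is undefined).
#'
#' @param g1,g2 numeric vectors, each of length >= 3.
#' @return object of class `group_comparison` with `p_ttest`, `p_wilcoxon`,
#'   `p_normality_g1`, `p_normality_g2`.
#' @export
compare_groups <- function(g1, g2) {
  stopifnot(length(g1) >= 3L, length(g2) >= 3L)
  p_t <- if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
    if (mean(g1) == mean(g2)) 1 else NA_real_
  } else stats::t.test(g1, g2, var.equal = FALSE)$p.value
  ties <- anyDuplicated(c(g1, g2)) > 0L
  exact <- length(g1) <= 8L && length(g2) <= 8L && !ties
  p_w <- suppressWarnings(
    stats::wilcox.test(g1, g2, exact = exact, correct = !exact)$p.value)
  shp <- function(g) {
    if (stats::sd(g) == 0 || length(g) < 3L || length(g) > 5000L)
      return(NA_real_)
    stats::shapiro.test(g)$p.value
  }
  structure(list(p_ttest = p_t, p_wilcoxon = p_w,
                 p_normality_g1 = shp(g1), p_normality_g2 = shp(g2)),
            class = "group_comparison")
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson R and two-sided p per variable pair under pairwise-complete
#' deletion; pairs with fewer than 3 complete cases are left NA.
#'
#' @param data data.frame of numeric columns.
#' @param variables columns to include; default all numeric columns.
#' @return object of class `correlation_matrix` with matrices `r`, `p` and
#'   `n`.
#' @export
correlation_matrix <- function(data, variables = NULL) {
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, TRUE)]
  stopifnot(length(variables) >= 2L, all(variables %in% names(data)))
  k <- length(variables)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    x <- data[[variables[i]]]; y <- data[[variables[j]]]
    ok <- is.finite(x) & is.finite(y)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  diag(nmat) <- vapply(variables, function(v) sum(is.finite(data[[v]])), 0)
  structure(list(variables = variables, r = r, p = p, n = nmat),
            class = "correlation_matrix")
}

#' Univariable linear regression
#'
#' Ordinary least squares of `y` on a single predictor: slope, intercept,
#' R^2, two-sided slope p-value, slope standard error and sample size.
#'
#' @param x,y numeric vectors; incomplete cases are dropped listwise.
#' @return list of class `regression_univariable`.
#' @export
fit_univariable <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("univariable regression needs n >= 3")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 std_err = sm$coefficients[2, 2],
                 n = length(x)),
            class = "regression_univariable")
}

#' Multivariable linear regression
#'
#' Ordinary least squares with intercept on a matrix/data.frame of
#' predictors: per-variable coefficients and p-values, R^2 and the
#' probability of the model F statistic. Exactly collinear designs are
#' refused, naming the dependent columns.
#'
#' @param X data.frame or matrix of predictors.
#' @param y numeric response.
#' @return list of class `regression_multivariable`.
#' @export
fit_multivariable <- function(X, y) {
  X <- as.data.frame(X)
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  k <- ncol(X)
  if (length(y) <= k + 1L) stop("need n > k + 1 observations")
  fit <- stats::lm(y ~ ., data = X)
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("collinear predictors: ", paste(names(co)[is.na(co)], collapse = ", "))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  f_prob <- if (is.null(fstat)) NA_real_
            else stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(coefficients = co[-1],
                 intercept = unname(co[1]),
                 p_values = sm$coefficients[-1, 4],
                 intercept_p = sm$coefficients[1, 4],
                 r_squared = sm$r.squared,
                 f_prob = unname(f_prob),
                 n = length(y)),
            class = "regression_multivariable")
}

#' @export
print.regression_multivariable <- function(x, ...) {
  cat(sprintf("Multivariable OLS (n = %d): R^2 = %.3f, F prob = %.3g\n",
              x$n, x$r_squared, x$f_prob))
  tab <- data.frame(variable = c("(Intercept)", names(x$coefficients)),
                    coefficient = c(x$intercept, unname(x$coefficients)),
                    p_value = c(x$intercept_p, unname(x$p_values)))
  print(tab, row.names = FALSE)
  invisible(x)
}
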