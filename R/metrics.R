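#' Relative deviation of an estimated TIA from its reference
#'
#' `(etia - rtia) / rtia`, dimensionless; vectorized.
#'
#' @param etia Estimated TIA value(s), hours.
#' @param rtia Reference TIA value(s), hours; must be positive.
#' @return Relative deviation(s).
#' @export
relative_deviation <- function(etia, rtia) {
  if (any(!is.finite(rtia)) || any(rtia <= 0))
    stop("'rtia' must be positive", call. = FALSE)
  (etia - rtia) / rtia
}

#' Propagated SD of a relative deviation
#'
#' First-order propagation treating the estimated and reference TIAs as
#' uncorrelated:
#' `sqrt( (sd_e/rtia)^2 + (etia * sd_r / rtia^2)^2 )`.
#'
#' @inheritParams relative_deviation
#' @param sd_e,sd_r SDs of `etia` and `rtia`; non-negative.
#' @return SD of the relative deviation(s).
#' @export
rd_sd <- function(etia, sd_e, rtia, sd_r) {
  if (any(!is.finite(rtia)) || any(rtia <= 0))
    stop("'rtia' must be positive", call. = FALSE)
  if (any(sd_e < 0) || any(sd_r < 0))
    stop("SDs must be non-negative", call. = FALSE)
  sqrt((sd_e / rtia)^2 + (etia * sd_r / rtia^2)^2)
}

#' Root-mean-square error of a relative-deviation vector
#'
#' `sqrt( SD(rd)^2 + mean(rd)^2 )` with the SD taken over N (not N-1), which
#' reduces identically to `sqrt(mean(rd^2))`. The `denominator` switch
#' allows the N-1 convention for sensitivity checks.
#'
#' @param rd Vector of relative deviations; non-empty.
#' @param denominator `"n"` (default) or `"n-1"` for the SD term.
#' @return Dimensionless RMSE (multiply by 100 for percent).
#' @export
rmse <- function(rd, denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  if (length(rd) < 1L) stop("'rd' must be non-empty", call. = FALSE)
  if (denominator == "n") return(sqrt(mean(rd^2)))
  n <- length(rd)
  v <- if (n > 1L) stats::var(rd) else 0
  sqrt(v + mean(rd)^2)
}

#' Mean absolute percentage error of a relative-deviation vector
#'
#' `(100/N) * sum(|rd|)`, in percent.
#'
#' @param rd Vector of relative deviations; non-empty.
#' @return MAPE in percent.
#' @export
mape <- function(rd) {
  if (length(rd) < 1L) stop("'rd' must be non-empty", call. = FALSE)
  100 * mean(abs(rd))
}

#' Propagated SD of the RMSE
#'
#' Delta method on `RMSE = sqrt(mean(rd^2))`:
#' `sqrt( sum( (rd_m / (N * RMSE))^2 * sd_m^2 ) )`. If the RMSE is exactly
#' zero with non-zero input SDs the derivative is undefined; the limiting
#' magnitude `1/sqrt(N)` is used per component and a warning is raised.
#'
#' @param rd Relative deviations.
#' @param sd Their SDs (same length).
#' @return SD of the RMSE (dimensionless).
#' @export
rmse_sd <- function(rd, sd) {
  if (length(rd) != length(sd))
    stop("'rd' and 'sd' must have equal length", call. = FALSE)
  n <- length(rd)
  r <- rmse(rd)
  if (r == 0) {
    if (any(sd > 0)) {
      warning("RMSE is 0 with non-zero input SDs; using the limiting ",
              "derivative magnitude 1/sqrt(N)", call. = FALSE)
      return(sqrt(sum(sd^2 / n)))
    }
    return(0)
  }
  sqrt(sum((rd / (n * r))^2 * sd^2))
}

#' Propagated SD of the MAPE
#'
#' `(100/N) * sqrt(sum(sd_m^2))`; the sign of each `|rd_m|` derivative is
#' +/-1 and drops out of the variance (derivative magnitude 1 is used at
#' `rd_m = 0`).
#'
#' @inheritParams rmse_sd
#' @return SD of the MAPE in percent.
#' @export
mape_sd <- function(rd, sd) {
  if (length(rd) != length(sd))
    stop("'rd' and 'sd' must have equal length", call. = FALSE)
  (100 / length(rd)) * sqrt(sum(sd^2))
}

#' Counts of subjects beyond relative-deviation thresholds
#'
#' Number (and integer-rounded percentage) of subjects with `|rd|` strictly
#' greater than each threshold; defaults mirror the 10% / 20% accuracy
#' bands.
#'
#' @param rd Relative deviations.
#' @param thresholds Numeric thresholds on `|rd|`.
#' @return Data frame with `threshold`, `count`, `percent`.
#' @export
threshold_counts <- function(rd, thresholds = c(0.10, 0.20)) {
  if (length(rd) < 1L) stop("'rd' must be non-empty", call. = FALSE)
  counts <- vapply(thresholds, function(th) sum(abs(rd) > th), integer(1))
  data.frame(threshold = thresholds, count = counts,
             percent = as.integer(round(100 * counts / length(rd))))
}

#' Coefficient of variation of a TIA estimate
#'
#' `sd / tia`, the per-subject precision measure; vectorized.
#'
#' @param tia TIA value(s), positive.
#' @param sd SD(s) of the TIA, non-negative.
#' @return Dimensionless CV(s).
#' @export
cv <- function(tia, sd) {
  if (any(!is.finite(tia)) || any(tia <= 0))
    stop("'tia' must be positive", call. = FALSE)
  if (any(sd < 0)) stop("'sd' must be non-negative", call. = FALSE)
  sd / tia
}

#' Summary of per-subject CVs for one method
#'
#' @param cvs Vector of per-subject CVs.
#' @return Data frame with `mean`, `sd`, `median`, `min`, `max`.
#' @export
cv_summary <- function(cvs) {
  if (length(cvs) < 1L) stop("'cvs' must be non-empty", call. = FALSE)
  data.frame(mean = mean(cvs),
             sd = if (length(cvs) > 1L) stats::sd(cvs) else 0,
             median = stats::median(cvs), min = min(cvs), max = max(cvs))
}

#' Simple linear regression of estimated on reference TIAs
#'
#' Ordinary least squares of `etia` on `rtia` with the two-sided t-test of
#' the slope against zero.
#'
#' @param etia,rtia Paired TIA vectors, length >= 3.
#' @return List with `slope`, `intercept`, `p_slope`, `r_squared`.
#' @export
ols_slope_test <- function(etia, rtia) {
  if (length(etia) != length(rtia) || length(etia) < 3L)
    stop("need paired vectors of length >= 3", call. = FALSE)
  if (stats::sd(rtia) == 0)
    stop("'rtia' has zero variance; regression is degenerate", call. = FALSE)
  fit <- stats::lm(etia ~ rtia)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p_slope = unname(sm$coefficients["rtia", "Pr(>|t|)"]),
       r_squared = sm$r.squared)
}

#' Full accuracy report for one dosimetry method
#'
#' Combines the relative deviations of the estimated TIAs against the
#' references with propagated uncertainties, RMSE/MAPE summaries, threshold
#' counts and the eTIA-vs-rTIA regression.
#'
#' @param etia,sd_e Estimated TIAs and their SDs (NA SDs are treated as 0
#'   in the propagation).
#' @param rtia,sd_r Reference TIAs and their SDs.
#' @param method Label carried into the report.
#' @return Object of class `accuracy_report` (a list): `method`, `n`, `rd`,
#'   `rd_sd`, `rd_median`, `rd_min`, `rd_max`, `rmse`, `rmse_sd`, `mape`,
#'   `mape_sd`, `rd10`, `rd20` (counts) with `rd10_pct`, `rd20_pct`, and
#'   `regression`.
#' @export
accuracy_report <- function(etia, sd_e, rtia, sd_r, method = "method") {
  n <- length(etia)
  stopifnot(length(rtia) == n, length(sd_e) == n, length(sd_r) == n, n >= 1L)
  sd_e <- ifelse(is.na(sd_e), 0, sd_e)
  sd_r <- ifelse(is.na(sd_r), 0, sd_r)
  rd <- relative_deviation(etia, rtia)
  rsd <- rd_sd(etia, sd_e, rtia, sd_r)
  th <- threshold_counts(rd)
  reg <- if (n >= 3L && stats::sd(rtia) > 0) ols_slope_test(etia, rtia)
         else NULL
  structure(list(
    method = method, n = n, rd = rd, rd_sd = rsd,
    rd_median = stats::median(rd), rd_min = min(rd), rd_max = max(rd),
    rmse = rmse(rd), rmse_sd = rmse_sd(rd, rsd),
    mape = mape(rd), mape_sd = mape_sd(rd, rsd),
    rd10 = th$count[1L], rd10_pct = th$percent[1L],
    rd20 = th$count[2L], rd20_pct = th$percent[2L],
    regression = reg
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "%s: N=%d  RD median %.1f%% [%.1f, %.1f]  RMSE %.1f (%.1f)%%  MAPE %.1f (%.1f)%%  RD10 %d (%d%%)  RD20 %d (%d%%)\n",
    x$method, x$n, 100 * x$rd_median, 100 * x$rd_min, 100 * x$rd_max,
    100 * x$rmse, 100 * x$rmse_sd, x$mape, x$mape_sd,
    x$rd10, x$rd10_pct, x$rd20, x$rd20_pct))
  invisible(x)
}
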