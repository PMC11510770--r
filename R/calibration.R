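# Field calibration of raw sensor signals against a reference analyser,
# and the network validation metrics.
#
# The validation metrics follow the conventions used in the sensor QA/QC
# literature this package targets: RMSE with an N-1 denominator, and a
# coefficient of determination whose denominator sums squared deviations of
# the *sensor* readings from the *mean reference* reading. The latter is
# not the textbook R^2 (it can exceed it or go negative for poor fits); a
# standard Pearson-r^2 variant is available behind `method = "pearson"`.

align_pairs <- function(sensor, ref) {
  if (inherits(sensor, "nox_ts") && inherits(ref, "nox_ts")) {
    if (nrow(sensor) != nrow(ref) ||
        any(as.numeric(sensor$time) != as.numeric(ref$time)))
      stop("sensor and reference series are not on the same grid",
           call. = FALSE)
    sensor <- sensor$value; ref <- ref$value
  }
  if (length(sensor) != length(ref))
    stop("paired series must have equal length", call. = FALSE)
  ok <- !is.na(sensor) & !is.na(ref)
  list(s = as.numeric(sensor[ok]), r = as.numeric(ref[ok]))
}

#' Root mean squared error between sensor and reference
#'
#' `sqrt(sum((sensor - ref)^2) / (N - 1))` over paired non-missing samples
#' (note the N-1 denominator, the convention adopted throughout this
#' package's validation metrics).
#'
#' @param sensor,ref numeric vectors or `nox_ts` on the same grid.
#' @return RMSE in ug/m3.
#' @export
rmse <- function(sensor, ref) {
  p <- align_pairs(sensor, ref)
  n <- length(p$s)
  if (n < 2) stop("rmse requires at least 2 paired samples", call. = FALSE)
  sqrt(sum((p$s - p$r)^2) / (n - 1))
}

#' Coefficient of determination between sensor and reference
#'
#' With `method = "as_reported"` (default):
#' `1 - sum((sensor - ref)^2) / sum((sensor - mean(ref))^2)`,
#' i.e. residuals against deviations of the sensor values from the mean
#' reference reading. `method = "pearson"` gives the squared Pearson
#' correlation instead.
#'
#' @inheritParams rmse
#' @param method `"as_reported"` or `"pearson"`.
#' @return dimensionless; at most 1, possibly negative for poor fits.
#' @export
r_squared <- function(sensor, ref, method = c("as_reported", "pearson")) {
  method <- match.arg(method)
  p <- align_pairs(sensor, ref)
  if (length(p$s) < 2)
    stop("r_squared requires at least 2 paired samples", call. = FALSE)
  if (method == "pearson") {
    if (stats::sd(p$s) == 0 || stats::sd(p$r) == 0)
      stop("r_squared undefined: a series is constant", call. = FALSE)
    return(stats::cor(p$s, p$r)^2)
  }
  denom <- sum((p$s - mean(p$r))^2)
  if (denom == 0)
    stop("r_squared undefined: zero denominator", call. = FALSE)
  1 - sum((p$s - p$r)^2) / denom
}

subset_window <- function(df, window) {
  if (is.null(window)) return(df)
  w <- as.POSIXct(window, tz = attr(df$time[1], "tzone"))
  df[df$time >= w[1L] & df$time < w[2L], , drop = FALSE]
}

#' Fit a field-calibration model against a reference analyser
#'
#' Ordinary least squares of `ref ~ 1 + raw + temperature + rh` over the
#' paired non-missing samples in the calibration window. The default
#' working resolution is hourly means (the resolution at which reference
#' analysers report); pass minute-cadence series through
#' \code{\link{hourly_aggregate}} first or set `min_pairs` accordingly.
#'
#' @param raw raw sensor `nox_ts`.
#' @param met data frame with `time`, `temperature_c`, `rh_pct` covering
#'   the raw grid (a `met_series`, possibly hourly-averaged).
#' @param ref reference `nox_ts` on the same grid as `raw`.
#' @param window optional `c(start, end)` calibration window (half-open).
#' @param min_pairs minimum paired samples; default 48, i.e. 48 h of
#'   hourly data, the minimum colocation duration used in network
#'   validation practice.
#' @return object of class `nox_calib` wrapping the `lm` fit, with
#'   `coef()`, `print()`, `residuals()` and \code{\link{apply_calibration}}.
#' @export
fit_calibration <- function(raw, met, ref, window = NULL, min_pairs = 48) {
  stopifnot(inherits(raw, "nox_ts"), inherits(ref, "nox_ts"))
  df <- data.frame(time = raw$time, raw = raw$value)
  df$ref <- ref$value[match(as.numeric(raw$time), as.numeric(ref$time))]
  mi <- match(as.numeric(raw$time), as.numeric(met$time))
  if (anyNA(mi))
    stop("met series does not cover the raw grid", call. = FALSE)
  df$temperature <- met$temperature_c[mi]
  df$rh <- met$rh_pct[mi]
  df <- subset_window(df, window)
  df <- df[stats::complete.cases(df[c("raw", "ref", "temperature", "rh")]), ]
  if (nrow(df) < max(min_pairs, 4))
    stop(sprintf("insufficient paired data for calibration: %d pairs, need %d",
                 nrow(df), max(min_pairs, 4)), call. = FALSE)
  for (cl in c("raw", "temperature", "rh"))
    if (stats::sd(df[[cl]]) == 0)
      stop("degenerate design: column '", cl, "' is constant over the window",
           call. = FALSE)
  X <- cbind(1, df$raw, df$temperature, df$rh)
  if (qr(X)$rank < 4L)
    stop("degenerate design: regressors are collinear over the window",
         call. = FALSE)
  fit <- stats::lm(ref ~ raw + temperature + rh, data = df)
  structure(list(
    fit = fit,
    coefficients = c(intercept = unname(stats::coef(fit)[1L]),
                     coef_signal = unname(stats::coef(fit)["raw"]),
                     coef_temperature = unname(stats::coef(fit)["temperature"]),
                     coef_rh = unname(stats::coef(fit)["rh"])),
    n_obs = nrow(df),
    fit_window = range(df$time),
    pollutant = attr(raw, "pollutant"),
    site_id = attr(raw, "site_id")),
    class = "nox_calib")
}

#' @export
print.nox_calib <- function(x, ...) {
  cat(sprintf("<nox_calib> site %s %s: n = %d, window %s .. %s\n",
              x$site_id, x$pollutant, x$n_obs,
              format(x$fit_window[1L]), format(x$fit_window[2L])))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.nox_calib <- function(object, ...) object$coefficients

#' @export
residuals.nox_calib <- function(object, ...) stats::residuals(object$fit)

#' @export
summary.nox_calib <- function(object, ...) summary(object$fit)

#' Confidence intervals for calibration coefficients
#' @param object a `nox_calib`.
#' @param parm,level see [stats::confint].
#' @param ... unused.
#' @export
confint.nox_calib <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$fit, level = level)
}

#' Apply a fitted calibration to a raw series
#'
#' `value = intercept + coef_signal * raw + coef_T * T + coef_RH * RH`,
#' clipped at zero (negative concentrations are not physical after
#' calibration); missing raw or met samples propagate as missing.
#'
#' @param model a `nox_calib`.
#' @param raw raw sensor `nox_ts`.
#' @param met met series covering `raw`'s grid.
#' @return calibrated `nox_ts` (never negative).
#' @export
apply_calibration <- function(model, raw, met) {
  stopifnot(inherits(model, "nox_calib"), inherits(raw, "nox_ts"))
  mi <- match(as.numeric(raw$time), as.numeric(met$time))
  if (anyNA(mi))
    stop("met series grid does not cover the raw series grid", call. = FALSE)
  b <- model$coefficients
  v <- b[["intercept"]] + b[["coef_signal"]] * raw$value +
    b[["coef_temperature"]] * met$temperature_c[mi] +
    b[["coef_rh"]] * met$rh_pct[mi]
  m <- ts_meta(raw)
  nox_ts(raw$time, pmax(v, 0), m$site_id, m$pollutant, m$cadence)
}

#' @export
predict.nox_calib <- function(object, raw, met, ...) {
  apply_calibration(object, raw, met)
}

#' Validation metrics for a sensor/reference pair
#'
#' @inheritParams rmse
#' @return one-row data frame: `r2`, `rmse`, `n`.
#' @export
validation_metrics <- function(sensor, ref) {
  p <- align_pairs(sensor, ref)
  data.frame(r2 = r_squared(p$s, p$r), rmse = rmse(p$s, p$r),
             n = length(p$s))
}

#' Screen a calibration window for valid conditions
#'
#' Warns (does not fail) when the window violates recommended field
#' calibration practice: maximum reference concentration below 50 ppb,
#' sustained relative humidity above 80%, or temperatures outside
#' 5-35 degC.
#'
#' @param ref reference `nox_ts` over the window.
#' @param met met series over the window.
#' @param sustained_hours RH exceedance duration (hours) considered
#'   "prolonged" at hourly cadence.
#' @return invisibly, a named logical vector of checks passed.
#' @export
check_calibration_conditions <- function(ref, met, sustained_hours = 6) {
  pollutant <- attr(ref, "pollutant")
  max_ppb <- max(ref$value, na.rm = TRUE) / ppb_to_ugm3(1, pollutant)
  ok_range <- max_ppb > 50
  if (!ok_range)
    warning(sprintf(
      "max %s concentration %.1f ppb <= 50 ppb: regression may be weak",
      pollutant, max_ppb), call. = FALSE)
  r <- rle(met$rh_pct > 80)
  ok_rh <- !any(r$values & r$lengths >= sustained_hours)
  if (!ok_rh)
    warning("prolonged RH > 80% in calibration window", call. = FALSE)
  ok_temp <- all(met$temperature_c >= 5 & met$temperature_c <= 35,
                 na.rm = TRUE)
  if (!ok_temp)
    warning("temperature outside 5-35 degC in calibration window",
            call. = FALSE)
  invisible(c(concentration_range = ok_range, rh = ok_rh,
              temperature = ok_temp))
}

#' Hourly-average a met series
#'
#' Companion to \code{\link{hourly_aggregate}} for the temperature/RH
#' channels (plain means of non-missing minutes).
#'
#' @param met minute-cadence `met_series`.
#' @return hourly `met_series`.
#' @export
hourly_aggregate_met <- function(met) {
  hour <- trunc(met$time, units = "hours")
  grid <- time_grid(hour[1L], hour[length(hour)], "hour")
  f <- match(as.numeric(hour), as.numeric(grid))
  agg <- function(v) {
    out <- rep(NA_real_, length(grid))
    m <- tapply(v, f, mean, na.rm = TRUE)
    out[as.integer(names(m))] <- m
    out
  }
  structure(data.frame(time = grid, temperature_c = agg(met$temperature_c),
                       rh_pct = agg(met$rh_pct)),
            class = c("met_series", "data.frame"))
}
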