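# Lowest-percentile baseline separation.
#
# The measured concentration at a site is the sum of a slowly varying
# regional background and sharp local emission transients. A low quantile
# of each fixed 8-hour window is unlikely to be touched by local plumes,
# so those window anchors trace the background; smoothing them with a
# penalized (thin-plate basis) regression spline yields a continuous,
# time-varying baseline, and total - baseline is the local signal.

#' Configuration for baseline separation
#'
#' @param window_hours window width in hours; must divide 24 so windows
#'   tile the day (default 8: windows 00-08, 08-16, 16-24 local time,
#'   matching common work-shift rhythms).
#' @param anchor_quantile quantile in (0, 0.5] taken within each window
#'   (default 0.01 - effectively the window minimum, but robust to
#'   single-sample sensor glitches; values approaching 0 reproduce the
#'   literal minimum).
#' @param smoother `"thin_plate"` (penalized regression spline with
#'   thin-plate basis, via mgcv) or `"penalized_cubic"` (cubic smoothing
#'   spline).
#' @param smoothing_selection `"gcv"` (generalized cross-validation,
#'   default) or `"fixed"` (supply `sp`).
#' @param sp fixed smoothing parameter when `smoothing_selection = "fixed"`.
#' @param clip_local_at_zero clip the local signal at zero (default TRUE;
#'   negative local emission is not physical). The unclipped signal is
#'   retained for conservation audits.
#' @param min_window_coverage minimum fraction of non-missing minutes for
#'   a window to contribute an anchor (default 0.5).
#' @param fraction_mode `"ratio_of_means"` (default: one fraction per
#'   series, 100 * mean(local) / mean(total)) or `"mean_of_ratios"`.
#' @return list of class `baseline_config`.
#' @export
baseline_config <- function(window_hours = 8,
                            anchor_quantile = 0.01,
                            smoother = c("thin_plate", "penalized_cubic"),
                            smoothing_selection = c("gcv", "fixed"),
                            sp = NULL,
                            clip_local_at_zero = TRUE,
                            min_window_coverage = 0.5,
                            fraction_mode = c("ratio_of_means",
                                              "mean_of_ratios")) {
  smoother <- match.arg(smoother)
  smoothing_selection <- match.arg(smoothing_selection)
  fraction_mode <- match.arg(fraction_mode)
  if (24 %% window_hours != 0)
    stop("window_hours must divide 24 so windows tile the day",
         call. = FALSE)
  if (!(anchor_quantile > 0 && anchor_quantile <= 0.5))
    stop("anchor_quantile must be in (0, 0.5]", call. = FALSE)
  if (smoothing_selection == "fixed" && is.null(sp))
    stop("smoothing_selection = 'fixed' requires `sp`", call. = FALSE)
  structure(list(window_hours = window_hours,
                 anchor_quantile = anchor_quantile,
                 smoother = smoother,
                 smoothing_selection = smoothing_selection, sp = sp,
                 clip_local_at_zero = clip_local_at_zero,
                 min_window_coverage = min_window_coverage,
                 fraction_mode = fraction_mode),
            class = "baseline_config")
}

#' Segment a minute series into consecutive day-tiling windows
#'
#' Windows are non-overlapping, midnight-anchored in local time
#' (00-08, 08-16, 16-24 for the 8-hour default). A window whose
#' non-missing coverage falls below `min_window_coverage` is flagged
#' invalid and contributes no anchor.
#'
#' @param ts minute-cadence `nox_ts`.
#' @param config a `baseline_config`.
#' @return data frame: `window` (index), `start`, `center`, `n_total`,
#'   `n_valid`, `valid`.
#' @export
segment_windows <- function(ts, config = baseline_config()) {
  stopifnot(inherits(ts, "nox_ts"))
  if (attr(ts, "cadence") != "minute")
    stop("segment_windows() expects a minute-cadence series", call. = FALSE)
  w_sec <- config$window_hours * 3600
  day0 <- trunc(ts$time, units = "days")
  secs <- as.numeric(ts$time) - as.numeric(day0)
  slot <- floor(secs / w_sec)                 # window-of-day index
  start <- day0 + slot * w_sec
  key <- as.numeric(start)
  ukey <- sort(unique(key))
  f <- match(key, ukey)
  n_total <- as.integer(tapply(f, f, length))
  n_valid <- as.integer(tapply(!is.na(ts$value), f, sum))
  full <- config$window_hours * 60            # coverage vs the full window
  data.frame(window = seq_along(ukey),
             start = as.POSIXct(ukey, tz = attr(ts$time, "tzone"),
                                origin = "1970-01-01"),
             center = as.POSIXct(ukey + w_sec / 2,
                                 tz = attr(ts$time, "tzone"),
                                 origin = "1970-01-01"),
             n_total = n_total, n_valid = n_valid,
             valid = n_valid >= config$min_window_coverage * full)
}

#' Low-quantile anchors of each valid window
#'
#' The anchor value is the empirical quantile (linear interpolation
#' between order statistics) of the window's non-missing values at
#' `anchor_quantile`; the anchor time is the window midpoint. Invalid
#' windows get a missing anchor.
#'
#' @inheritParams segment_windows
#' @return data frame: `window`, `center`, `value` (NA when invalid).
#' @export
window_anchors <- function(ts, config = baseline_config()) {
  win <- segment_windows(ts, config)
  w_sec <- config$window_hours * 3600
  idx <- findInterval(as.numeric(ts$time), as.numeric(win$start))
  vals <- vapply(seq_len(nrow(win)), function(i) {
    if (!win$valid[i]) return(NA_real_)
    v <- ts$value[idx == i]
    stats::quantile(v, probs = config$anchor_quantile, na.rm = TRUE,
                    names = FALSE, type = 7)
  }, numeric(1))
  data.frame(window = win$window, center = win$center, value = vals)
}

#' Smooth window anchors into a continuous baseline
#'
#' Fits a penalized regression spline (thin-plate basis, smoothing
#' parameter by GCV unless fixed) through the valid anchors and evaluates
#' it on the full series grid; the result is clipped at zero. Diagnostics
#' report the largest overshoot of the curve beyond the range of
#' neighbouring anchor values.
#'
#' @param anchors data frame from \code{\link{window_anchors}}.
#' @param grid_times POSIXct grid on which to evaluate the baseline.
#' @param config a `baseline_config`.
#' @return `nox_ts`-shaped data frame? No: a list with `values` (numeric
#'   baseline on `grid_times`), `at_anchors` (fitted values at anchor
#'   times) and `overshoot` (max excursion beyond neighbouring anchor
#'   range, ug/m3).
#' @export
fit_baseline <- function(anchors, grid_times, config = baseline_config()) {
  ok <- !is.na(anchors$value)
  n <- sum(ok)
  if (n < 4)
    stop("insufficient anchors for baseline smoothing: ", n, " < 4",
         call. = FALSE)
  t0 <- as.numeric(grid_times[1L])
  x <- (as.numeric(anchors$center[ok]) - t0) / 3600   # hours from start
  y <- anchors$value[ok]
  xg <- (as.numeric(grid_times) - t0) / 3600
  if (config$smoother == "thin_plate") {
    k <- max(4, min(n - 1, 60))
    sp <- if (config$smoothing_selection == "fixed") config$sp else NULL
    fit <- mgcv::gam(y ~ s(x, bs = "tp", k = k), method = "GCV.Cp", sp = sp)
    pred <- as.numeric(mgcv::predict.gam(fit, newdata = data.frame(x = xg)))
    at_anchor <- as.numeric(stats::fitted(fit))
  } else {
    spar <- if (config$smoothing_selection == "fixed") config$sp else NULL
    fit <- if (is.null(spar)) stats::smooth.spline(x, y, cv = FALSE)
           else stats::smooth.spline(x, y, spar = spar)
    pred <- stats::predict(fit, xg)$y
    at_anchor <- stats::predict(fit, x)$y
  }
  # overshoot beyond the envelope of neighbouring anchors, between anchors
  seg <- findInterval(xg, x)
  inside <- seg >= 1 & seg < length(x)
  lo <- pmin(y[pmax(seg, 1)], y[pmin(seg + 1L, length(y))])
  hi <- pmax(y[pmax(seg, 1)], y[pmin(seg + 1L, length(y))])
  over <- max(c(0, (pmax(pred - hi, lo - pred))[inside]), na.rm = TRUE)
  list(values = pmax(pred, 0), at_anchors = at_anchor, overshoot = over)
}

#' Separate a series into regional baseline and local emission signal
#'
#' The core decomposition: low-quantile anchors of consecutive 8-hour
#' windows are smoothed into a time-varying regional baseline; the local
#' signal is `total - baseline` (clipped at zero by default, with the
#' unclipped signal retained). Contribution fractions are percentages of
#' the time-mean concentration.
#'
#' @param ts calibrated minute-cadence `nox_ts`.
#' @param config a `baseline_config`.
#' @return object of class `nox_decomp`: list with `data` (`time`,
#'   `total`, `baseline`, `local`, `local_unclipped`), `anchors`,
#'   `local_fraction`, `regional_fraction` (percent, summing to 100),
#'   `diagnostics` and `config`. Methods: `print`, `summary`, `plot`,
#'   `fitted` (baseline), `residuals` (local signal).
#' @examples
#' cfg <- scenario_config(n_days = 4, sites = default_sites()[8, ], seed = 7)
#' net <- generate_network(cfg)
#' d <- decompose(bundle_ts(net, "8", "NO", "total"))
#' d$local_fraction
#' @export
decompose <- function(ts, config = baseline_config()) {
  stopifnot(inherits(ts, "nox_ts"))
  if (all(is.na(ts$value)))
    stop("cannot decompose an all-missing series", call. = FALSE)
  anchors <- window_anchors(ts, config)
  fb <- fit_baseline(anchors, ts$time, config)
  baseline <- fb$values
  baseline[is.na(ts$value)] <- NA_real_
  local_raw <- ts$value - baseline
  local <- if (config$clip_local_at_zero) pmax(local_raw, 0) else local_raw
  ok <- !is.na(ts$value)
  lf <- if (config$fraction_mode == "ratio_of_means") {
    100 * mean(local[ok]) / mean(ts$value[ok])
  } else {
    pos <- ok & ts$value > 0
    100 * mean(local[pos] / ts$value[pos])
  }
  a_ok <- !is.na(anchors$value)
  viol <- fb$at_anchors - anchors$value[a_ok]   # baseline above anchor
  diagnostics <- list(
    overshoot = fb$overshoot,
    max_anchor_violation = max(c(0, viol)),
    max_anchor_violation_rel = max(c(0, viol / pmax(anchors$value[a_ok],
                                                    .Machine$double.eps))),
    n_anchors = sum(a_ok),
    conservation_max_abs = max(abs(((ts$value - baseline) - local_raw)[ok])))
  structure(list(data = data.frame(time = ts$time, total = ts$value,
                                   baseline = baseline, local = local,
                                   local_unclipped = local_raw),
                 anchors = anchors,
                 local_fraction = lf, regional_fraction = 100 - lf,
                 diagnostics = diagnostics, config = config,
                 site_id = attr(ts, "site_id"),
                 pollutant = attr(ts, "pollutant")),
            class = "nox_decomp")
}

#' @export
print.nox_decomp <- function(x, ...) {
  cat(sprintf("<nox_decomp> site %s %s: %d points, %d anchors\n",
              x$site_id, x$pollutant, nrow(x$data),
              x$diagnostics$n_anchors))
  cat(sprintf("  local %.1f%% / regional %.1f%% of time-mean concentration\n",
              x$local_fraction, x$regional_fraction))
  invisible(x)
}

#' @export
summary.nox_decomp <- function(object, ...) {
  ok <- !is.na(object$data$total)
  out <- list(
    site_id = object$site_id, pollutant = object$pollutant,
    n = sum(ok),
    mean_total = mean(object$data$total[ok]),
    mean_baseline = mean(object$data$baseline[ok]),
    mean_local = mean(object$data$local[ok]),
    baseline_range = range(object$data$baseline[ok]),
    local_fraction = object$local_fraction,
    regional_fraction = object$regional_fraction,
    diagnostics = object$diagnostics)
  class(out) <- "summary.nox_decomp"
  out
}

#' @export
print.summary.nox_decomp <- function(x, ...) {
  cat(sprintf("Baseline separation, site %s %s (n = %d)\n", x$site_id,
              x$pollutant, x$n))
  cat(sprintf("  mean total    %8.2f ug/m3\n", x$mean_total))
  cat(sprintf("  mean baseline %8.2f ug/m3 (range %.1f .. %.1f)\n",
              x$mean_baseline, x$baseline_range[1L], x$baseline_range[2L]))
  cat(sprintf("  mean local    %8.2f ug/m3\n", x$mean_local))
  cat(sprintf("  local / regional contribution: %.1f%% / %.1f%%\n",
              x$local_fraction, x$regional_fraction))
  cat(sprintf("  max baseline-above-anchor: %.3f ug/m3\n",
              x$diagnostics$max_anchor_violation))
  invisible(x)
}

#' @export
fitted.nox_decomp <- function(object, ...) object$data$baseline

#' @export
residuals.nox_decomp <- function(object, ...) object$data$local

#' Plot a baseline decomposition
#'
#' Total signal in grey, fitted regional baseline in blue, window anchors
#' as points.
#'
#' @param x a `nox_decomp`.
#' @param ... passed to [plot.default].
#' @export
plot.nox_decomp <- function(x, ...) {
  plot(x$data$time, x$data$total, type = "l", col = "grey60",
       xlab = "time", ylab = sprintf("%s (ug/m3)", x$pollutant),
       main = sprintf("Site %s: baseline separation", x$site_id), ...)
  graphics::lines(x$data$time, x$data$baseline, col = "blue", lwd = 2)
  graphics::points(x$anchors$center, x$anchors$value, pch = 19, cex = 0.6,
                   col = "red")
  graphics::legend("topright", bty = "n",
                   legend = c("total", "baseline", "anchors"),
                   col = c("grey60", "blue", "red"),
                   lty = c(1, 1, NA), pch = c(NA, NA, 19))
  invisible(x)
}
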