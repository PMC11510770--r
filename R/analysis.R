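# Spatiotemporal summarisation: descriptive statistics, diurnal profiles,
# functional-zone averages, NO/NOx oxidation ratios, unit conversion.

#' Descriptive statistics of a concentration series
#'
#' 25th percentile, median, mean, 75th percentile (quantiles by linear
#' interpolation between order statistics), standard deviation (N-1
#' denominator) and sample count, over the non-missing values.
#'
#' @param x numeric vector or `nox_ts`.
#' @return one-row data frame of class `summary_stats`:
#'   `p25`, `median`, `mean`, `p75`, `sd`, `n`.
#' @export
descriptive_stats <- function(x) {
  if (inherits(x, "nox_ts")) x <- x$value
  v <- x[!is.na(x)]
  if (length(v) < 2)
    stop("descriptive_stats requires at least 2 non-missing values",
         call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(data.frame(p25 = q[1L], median = q[2L], mean = mean(v),
                       p75 = q[3L], sd = stats::sd(v), n = length(v)),
            class = c("summary_stats", "data.frame"))
}

#' Total NOx mass concentration
#'
#' NOx from mobile combustion sources is, to good approximation, NO plus
#' NO2; both channels are carried in ug/m3, so NOx is their plain sum.
#'
#' @param no_mean,no2_mean mean NO and NO2 concentrations (ug/m3, >= 0).
#' @return NOx in ug/m3.
#' @export
nox_total <- function(no_mean, no2_mean) {
  if (any(no_mean < 0) || any(no2_mean < 0))
    stop("concentrations must be nonnegative", call. = FALSE)
  no_mean + no2_mean
}

#' NO/NOx oxidation ratio
#'
#' Fraction of NOx present as NO; values near 1 indicate fresh,
#' little-oxidised emissions close to the source.
#'
#' @inheritParams nox_total
#' @return `no_mean / (no_mean + no2_mean)`, in (0, 1].
#' @export
no_nox_ratio <- function(no_mean, no2_mean) {
  tot <- nox_total(no_mean, no2_mean)
  if (any(tot == 0))
    stop("NO/NOx ratio undefined: NO + NO2 is zero", call. = FALSE)
  no_mean / tot
}

#' Mean diurnal profile of an hourly series
#'
#' Per-hour-of-day mean (local time) over all days; hours with no valid
#' sample are marked missing.
#'
#' @param ts hour-cadence `nox_ts` with local-time timestamps.
#' @return data frame of class `diurnal_profile`: `hour` (0..23), `mean`,
#'   `n`.
#' @export
diurnal_profile <- function(ts) {
  stopifnot(inherits(ts, "nox_ts"))
  if (attr(ts, "cadence") != "hour")
    stop("diurnal_profile() expects an hourly series; see hourly_aggregate()",
         call. = FALSE)
  hr <- as.integer(format(ts$time, "%H"))
  out <- data.frame(hour = 0:23, mean = NA_real_, n = 0L)
  for (h in 0:23) {
    v <- ts$value[hr == h]
    v <- v[!is.na(v)]
    out$n[h + 1L] <- length(v)
    if (length(v)) out$mean[h + 1L] <- mean(v)
  }
  structure(out, class = c("diurnal_profile", "data.frame"))
}

#' Pooled statistics for one functional zone
#'
#' Default pooling concatenates all samples from the zone's sites into one
#' distribution; `mode = "site_means"` averages per-site means instead
#' (statistics are then computed over the site means).
#'
#' @param x data frame with at least `site_id` and `value` columns (one
#'   concentration sample per row).
#' @param meta `site_meta` table.
#' @param zone functional zone code.
#' @param mode `"pooled"` or `"site_means"`.
#' @return `summary_stats` row.
#' @export
zone_average <- function(x, meta, zone, mode = c("pooled", "site_means")) {
  mode <- match.arg(mode)
  sites <- meta$site_id[meta$zone == zone]
  if (!length(sites)) stop("no sites in zone ", zone, call. = FALSE)
  v <- x$value[x$site_id %in% sites]
  if (mode == "site_means")
    v <- vapply(split(x$value[x$site_id %in% sites],
                      x$site_id[x$site_id %in% sites]),
                mean, numeric(1), na.rm = TRUE)
  descriptive_stats(v)
}

#' Convert ppb to ug/m3 from the ideal gas law
#'
#' `value * MW / (R T / P)` with MW(NO) = 30.006 and MW(NO2) = 46.0055
#' g/mol, R = 0.082057 L atm / (mol K). At 20 degC and 1 atm the factors
#' round to 1.25 (NO) and 1.91 (NO2) ug/m3 per ppb.
#'
#' @param value mixing ratio in ppb (>= 0).
#' @param gas `"NO"` or `"NO2"`.
#' @param temperature_c temperature in degC (default 20).
#' @param pressure_atm pressure in atm (default 1).
#' @return mass concentration in ug/m3.
#' @export
ppb_to_ugm3 <- function(value, gas = c("NO", "NO2"), temperature_c = 20,
                        pressure_atm = 1) {
  gas <- match.arg(gas)
  if (any(value < 0)) stop("value must be >= 0", call. = FALSE)
  if (any(temperature_c <= -273.15))
    stop("temperature below absolute zero", call. = FALSE)
  mw <- c(NO = 30.006, NO2 = 46.0055)[[gas]]
  molar_volume <- 0.082057 * (temperature_c + 273.15) / pressure_atm # L/mol
  value * mw / molar_volume
}

#' Site-level summary table for a network
#'
#' One row per (site, pollutant) with the descriptive statistics of the
#' chosen channel - the schema of a campaign summary table.
#'
#' @param bundle a `truth_bundle` (or any long data frame with `site_id`,
#'   `pollutant` and the chosen value column).
#' @param channel column to summarise (default `"total"`).
#' @return data frame: `site_id`, `pollutant`, `p25`, `median`, `mean`,
#'   `p75`, `sd`, `n`.
#' @export
site_stats_table <- function(bundle, channel = "total") {
  d <- if (inherits(bundle, "truth_bundle")) bundle$data else bundle
  groups <- split(d[[channel]], list(d$site_id, d$pollutant), drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    parts <- strsplit(g, ".", fixed = TRUE)[[1L]]
    cbind(data.frame(site_id = parts[1L], pollutant = parts[2L]),
          as.data.frame(descriptive_stats(groups[[g]])))
  })
  out <- do.call(rbind, rows)
  out[order(suppressWarnings(as.numeric(out$site_id)), out$site_id,
            out$pollutant), , drop = FALSE]
}

#' Published site-level campaign statistics
#'
#' Descriptive statistics (25th percentile, median, mean, 75th percentile,
#' SD, in ug/m3) of NO and NO2 reported for a 17-site sensor-network
#' campaign across two container terminals, as printed in the campaign
#' summary table. Used to check NOx-sum and NO/NOx-ratio arithmetic
#' against the values reported alongside that table.
#'
#' @return data frame with columns `site_id` plus `no_*` and `no2_*`
#'   statistic columns.
#' @export
published_site_stats <- function() {
  path <- system.file("extdata", "port_site_stats.csv", package = "portnox",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' NOx means and NO/NOx ratios from a published-statistics table
#'
#' @param stats table from \code{\link{published_site_stats}}.
#' @return data frame: `site_id`, `no_mean`, `no2_mean`, `nox_mean`,
#'   `nox_rounded` (nearest integer, reporting convention), `ratio`,
#'   `ratio_1dp` (1-decimal reporting convention).
#' @export
site_nox_summary <- function(stats = published_site_stats()) {
  nox <- nox_total(stats$no_mean, stats$no2_mean)
  ratio <- no_nox_ratio(stats$no_mean, stats$no2_mean)
  data.frame(site_id = stats$site_id, no_mean = stats$no_mean,
             no2_mean = stats$no2_mean, nox_mean = nox,
             nox_rounded = round(nox), ratio = ratio,
             ratio_1dp = round(ratio, 1))
}
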