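# End-to-end validation experiments on synthetic scenarios: contribution
# fraction recovery, and sampling-distribution checks for the calibration
# regression. These power the package's self-tests and the reproduction
# script, and are exported so users can rerun them at other settings.

#' Local-fraction recovery experiment
#'
#' Generates single-site scenarios whose plume base rates span `rate_range`,
#' decomposes the true total NO series of each, and compares the estimated
#' local contribution fraction with the generator truth
#' `100 * mean(local) / mean(total)`.
#'
#' @param n_scenarios number of scenarios.
#' @param rate_range range of plume base rates (events/hour) to span.
#' @param n_days days per scenario.
#' @param seed base seed; scenario `i` uses `seed + i`.
#' @param config_fn optional function(rate, seed) returning a
#'   `scenario_config`, to override the default single-OA-site design.
#' @param baseline a `baseline_config` for the decomposition.
#' @return data frame: `rate`, `truth_pct`, `estimate_pct`, `error_pp`.
#' @export
local_fraction_recovery <- function(n_scenarios = 20,
                                    rate_range = c(0.6, 6),
                                    n_days = 5, seed = 1,
                                    config_fn = NULL,
                                    baseline = baseline_config()) {
  rates <- seq(rate_range[1L], rate_range[2L], length.out = n_scenarios)
  rows <- lapply(seq_len(n_scenarios), function(i) {
    cfg <- if (is.null(config_fn)) {
      cf <- scenario_config(n_days = n_days,
                            sites = site_meta("s1", "OA", "PCT2"),
                            seed = seed + i)
      cf$plumes$rate_per_hour[cf$plumes$zone == "OA"] <- rates[i]
      cf
    } else config_fn(rates[i], seed + i)
    net <- generate_network(cfg)
    sid <- cfg$sites$site_id[1L]
    tot <- bundle_ts(net, sid, "NO", "total")
    loc <- bundle_ts(net, sid, "NO", "local")
    truth <- 100 * mean(loc$value) / mean(tot$value)
    est <- decompose(tot, baseline)$local_fraction
    data.frame(rate = rates[i], truth_pct = truth, estimate_pct = est,
               error_pp = est - truth)
  })
  do.call(rbind, rows)
}

#' Zero-plume specificity experiment
#'
#' Decomposes a series that is exactly background (all plume rates zero)
#' and returns the regional fraction, which should stay near 100%: the
#' oscillating background must not be mistaken for local emission.
#'
#' @param n_days scenario length in days.
#' @param seed RNG seed.
#' @param baseline a `baseline_config`.
#' @return regional contribution fraction in percent.
#' @export
zero_plume_regional_fraction <- function(n_days = 7, seed = 1,
                                         baseline = baseline_config()) {
  cfg <- scenario_config(n_days = n_days,
                         sites = site_meta("s1", "OA", "PCT2"), seed = seed)
  cfg$plumes$rate_per_hour[] <- 0
  net <- generate_network(cfg)
  decompose(bundle_ts(net, "s1", "NO", "total"), baseline)$regional_fraction
}

#' Confidence-interval coverage of the calibration regression
#'
#' Repeatedly simulates a colocation experiment at hourly cadence (the
#' calibration working resolution), fits `ref ~ raw + T + RH`, and checks
#' whether each coefficient's 95% confidence interval covers the value
#' implied by the generating sensor model (`1/gain`, `-offset/gain`,
#' `-temp_coef/gain`, `-rh_coef/gain`). With correctly specified Gaussian
#' noise the empirical coverage should be close to the nominal level.
#'
#' @param n_rep number of replicates.
#' @param n_days colocation length per replicate (days).
#' @param seed base seed.
#' @param level confidence level.
#' @return list: `coverage` (overall fraction of covering intervals),
#'   `per_coef` (named coverage per coefficient), `n_rep`.
#' @export
calibration_coverage <- function(n_rep = 500, n_days = 5, seed = 1,
                                 level = 0.95) {
  base_cfg <- scenario_config(n_days = n_days,
                              sites = site_meta("c1", "BA", "PCT2",
                                                colocated = TRUE),
                              seed = seed)
  s <- base_cfg$sensor
  truth <- c(-s$offset / s$gain, 1 / s$gain, -s$temp_coef / s$gain,
             -s$rh_coef / s$gain)
  hits <- matrix(NA, n_rep, 4L,
                 dimnames = list(NULL, c("intercept", "coef_signal",
                                         "coef_temperature", "coef_rh")))
  for (r in seq_len(n_rep)) {
    cfg <- base_cfg
    cfg$seed <- as.integer(seed + r)
    net <- generate_network(cfg)
    raw_h <- hourly_aggregate(bundle_ts(net, "c1", "NO", "raw"))
    ref_h <- hourly_aggregate(bundle_ts(net, "c1", "NO", "total"))
    met_h <- hourly_aggregate_met(net$met)
    model <- fit_calibration(raw_h, met_h, ref_h)
    ci <- confint(model, level = level)
    hits[r, ] <- ci[, 1L] <= truth & truth <= ci[, 2L]
  }
  list(coverage = mean(hits), per_coef = colMeans(hits), n_rep = n_rep)
}

#' Implied calibration coefficients of a synthetic sensor
#'
#' Inverts the generating sensor model `raw = gain * true + offset +
#' temp_coef * T + rh_coef * RH (+ noise)` to the coefficients the
#' `ref ~ raw + T + RH` regression should recover.
#'
#' @param sensor the `sensor` list of a `scenario_config`.
#' @return named numeric vector matching `coef()` of a `nox_calib`.
#' @export
implied_calibration_coefs <- function(sensor) {
  c(intercept = -sensor$offset / sensor$gain,
    coef_signal = 1 / sensor$gain,
    coef_temperature = -sensor$temp_coef / sensor$gain,
    coef_rh = -sensor$rh_coef / sensor$gain)
}
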