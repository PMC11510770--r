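# Shared fixtures: tiny scenarios and grids built in code.

tz_test <- "Asia/Shanghai"

t_at <- function(s, tz = tz_test) as.POSIXct(s, tz = tz)

minute_grid <- function(n, start = "2023-10-21 00:00:00") {
  t_at(start) + 60 * (seq_len(n) - 1L)
}

# one-site scenario, optionally with overridden plume rate for that zone
tiny_scenario <- function(n_days = 3, zone = "OA", seed = 1, rate = NULL,
                          noise_sd = NULL) {
  cfg <- scenario_config(n_days = n_days,
                         sites = site_meta("s1", zone, "PCT2",
                                           colocated = TRUE),
                         seed = seed)
  if (!is.null(rate))
    cfg$plumes$rate_per_hour[cfg$plumes$zone == zone] <- rate
  if (!is.null(noise_sd)) cfg$sensor$noise_sd <- noise_sd
  cfg
}

# long-format CSV on disk from records; returns path
write_ts_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}
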