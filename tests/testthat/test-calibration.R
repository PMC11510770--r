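# Calibration regression and validation metrics.

# brute-force loop oracles, kept deliberately naive and separate from the
# vectorised implementations they check
rmse_loop <- function(s, r) {
  acc <- 0
  for (t in seq_along(s)) acc <- acc + (s[t] - r[t])^2
  sqrt(acc / (length(s) - 1))
}
r2_loop <- function(s, r) {
  rbar <- sum(r) / length(r)
  num <- 0; den <- 0
  for (t in seq_along(s)) {
    num <- num + (s[t] - r[t])^2
    den <- den + (s[t] - rbar)^2
  }
  1 - num / den
}

test_that("rmse follows the N-1 convention and quadratic behaviour", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  # hand evaluation: sensor (2,2), ref (0,2) -> sqrt(4/1) = 2
  expect_equal(rmse(c(2, 2), c(0, 2)), 2)
  # adding a constant to a zero-mean-residual pair strictly increases rmse
  set.seed(1)
  r <- rnorm(50)
  s <- r + rnorm(50)
  s <- s - mean(s - r)                       # residual mean exactly 0
  expect_gt(rmse(s + 3, r), rmse(s, r))
  expect_gt(rmse(s - 0.5, r), rmse(s, r))
  expect_error(rmse(1, 1), "at least 2")
})

test_that("r_squared matches its printed form, not the textbook one", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  # sensor constant at mean(ref), ref symmetric about its mean -> 0/0 denom
  # uses sensor deviations from mean(ref): denominator 0 -> undefined
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero denominator")
  # a non-constant sensor centred on mean(ref): hand evaluation
  s <- c(1, 3); r <- c(2, 2)               # num = 1+1, den = 1+1 -> 0
  expect_equal(r_squared(s, r), 0)
  # joint permutation invariance
  set.seed(2)
  s <- runif(30); r <- runif(30)
  p <- sample(30)
  expect_equal(r_squared(s, r), r_squared(s[p], r[p]))
  # pearson variant bounded in [0, 1] even when the printed form is negative
  expect_lte(r_squared(s, r, method = "pearson"), 1)
})

test_that("metrics agree with brute-force loop oracles to 1e-12 relative", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    s <- rnorm(n, 50, 20)
    r <- s + rnorm(n, 0, 5)
    expect_equal(rmse(s, r), rmse_loop(s, r), tolerance = 1e-12)
    expect_equal(r_squared(s, r), r2_loop(s, r), tolerance = 1e-12)
  }
})

test_that("noiseless linear sensors are recovered to machine precision", {
  # ref = 2 * raw + 5 exactly, with independent T/RH so the design is full
  # rank but the true T/RH coefficients are zero
  n <- 100
  g <- minute_grid(n)
  set.seed(3)
  raw_v <- runif(n, 0, 100)
  met <- data.frame(time = g, temperature_c = runif(n, 10, 25),
                    rh_pct = runif(n, 40, 90))
  raw <- nox_ts(g, raw_v, "s", "NO")
  ref <- nox_ts(g, 2 * raw_v + 5, "s", "NO")
  m <- fit_calibration(raw, met, ref, min_pairs = 10)
  expect_equal(unname(coef(m)), c(5, 2, 0, 0), tolerance = 1e-9)
  expect_equal(sum(residuals(m)), 0, tolerance = 1e-8)
})

test_that("full synthetic sensor model is inverted exactly without noise", {
  cfg <- tiny_scenario(n_days = 3, zone = "BA", seed = 9, noise_sd = 0)
  net <- generate_network(cfg)
  raw_h <- hourly_aggregate(bundle_ts(net, "s1", "NO", "raw"))
  ref_h <- hourly_aggregate(bundle_ts(net, "s1", "NO", "total"))
  m <- fit_calibration(raw_h, hourly_aggregate_met(net$met), ref_h)
  expect_equal(coef(m), implied_calibration_coefs(cfg$sensor),
               tolerance = 1e-9)
})

test_that("noisy synthetic calibration recovers coefficients within 3 SE", {
  cfg <- tiny_scenario(n_days = 5, zone = "BA", seed = 21, noise_sd = 2)
  net <- generate_network(cfg)
  raw_h <- hourly_aggregate(bundle_ts(net, "s1", "NO", "raw"))
  ref_h <- hourly_aggregate(bundle_ts(net, "s1", "NO", "total"))
  m <- fit_calibration(raw_h, hourly_aggregate_met(net$met), ref_h)
  truth <- implied_calibration_coefs(cfg$sensor)
  se <- summary(m)$coefficients[, "Std. Error"]
  expect_true(all(abs(coef(m) - truth) < 3.5 * se))
})

test_that("calibration reduces error against truth on a seeded scenario", {
  cfg <- tiny_scenario(n_days = 4, zone = "SR", seed = 31)
  net <- generate_network(cfg)
  raw <- bundle_ts(net, "s1", "NO", "raw")
  truth <- bundle_ts(net, "s1", "NO", "total")
  raw_h <- hourly_aggregate(raw)
  m <- fit_calibration(raw_h, hourly_aggregate_met(net$met),
                       hourly_aggregate(truth))
  cal <- apply_calibration(m, raw, net$met)
  expect_lt(rmse(cal, truth), rmse(raw, truth))
  expect_true(all(cal$value >= 0, na.rm = TRUE))
})

test_that("identity model clips at zero and propagates missing values", {
  g <- minute_grid(10)
  raw <- nox_ts(g, c(-3, -1, 0, 2, NA, 5, 7, NA, 1, -2), "s", "NO")
  met <- data.frame(time = g, temperature_c = 20, rh_pct = 50)
  m <- structure(list(coefficients = c(intercept = 0, coef_signal = 1,
                                       coef_temperature = 0, coef_rh = 0),
                      n_obs = 10, site_id = "s", pollutant = "NO"),
                 class = "nox_calib")
  out <- apply_calibration(m, raw, met)
  expect_equal(out$value, pmax(raw$value, 0))
  expect_identical(is.na(out$value), is.na(raw$value))
})

test_that("degenerate designs and short windows are rejected with clear errors", {
  n <- 60
  g <- minute_grid(n)
  set.seed(5)
  raw <- nox_ts(g, runif(n, 0, 100), "s", "NO")
  ref <- nox_ts(g, runif(n, 0, 100), "s", "NO")
  met_const_rh <- data.frame(time = g, temperature_c = runif(n, 10, 20),
                             rh_pct = 55)
  expect_error(fit_calibration(raw, met_const_rh, ref, min_pairs = 10),
               "'rh' is constant")
  met <- data.frame(time = g, temperature_c = runif(n, 10, 20),
                    rh_pct = runif(n, 40, 80))
  short <- nox_ts(g[1:10], raw$value[1:10], "s", "NO")
  expect_error(
    fit_calibration(short, met, nox_ts(g[1:10], ref$value[1:10], "s", "NO")),
    "insufficient paired data")
})

test_that("condition screening warns rather than fails", {
  g <- minute_grid(48)
  low <- nox_ts(g, rep(10, 48), "s", "NO")    # 10 ug/m3 = 8 ppb max
  wet <- data.frame(time = g, temperature_c = rep(40, 48),
                    rh_pct = rep(90, 48))
  expect_warning(expect_warning(expect_warning(
    check_calibration_conditions(low, wet),
    "50 ppb"), "RH"), "temperature")
  ok_met <- data.frame(time = g, temperature_c = rep(20, 48),
                       rh_pct = rep(60, 48))
  hot <- nox_ts(g, rep(100, 48), "s", "NO")
  expect_silent(check_calibration_conditions(hot, ok_met))
})
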