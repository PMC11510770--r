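# Descriptive statistics, NOx arithmetic, oxidation ratios, diurnal
# profiles, zone pooling and unit conversion.

stats_loop <- function(v) {
  # naive sort-based oracle for quantiles (linear interpolation, type 7)
  v <- sort(v)
  n <- length(v)
  qq <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  c(p25 = qq(0.25), median = qq(0.5), mean = mean(v), p75 = qq(0.75),
    sd = sqrt(sum((v - mean(v))^2) / (n - 1)))
}

test_that("descriptive statistics match a sort-based oracle", {
  s <- descriptive_stats(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$mean, 2.5)
  cst <- descriptive_stats(rep(4.2, 10))
  expect_equal(unlist(cst[c("p25", "median", "mean", "p75")]),
               c(p25 = 4.2, median = 4.2, mean = 4.2, p75 = 4.2))
  expect_equal(cst$sd, 0)
  set.seed(41)
  for (i in 1:20) {
    v <- rlnorm(sample(5:500, 1), 3, 1)
    got <- descriptive_stats(v)
    want <- stats_loop(v)
    expect_equal(unlist(got[names(want)]), want, tolerance = 1e-12)
    # order statistics are invariant under time permutation
    expect_equal(unlist(descriptive_stats(sample(v))[names(want)]), want)
  }
  expect_error(descriptive_stats(c(1, NA)), "at least 2")
})

test_that("published per-site NOx sums reproduce the reported values", {
  tab <- site_nox_summary()
  expect_equal(nrow(tab), 17L)
  got <- tab$nox_rounded[match(c(8, 15, 1, 7, 9), tab$site_id)]
  expect_equal(got, c(370, 341, 89, 122, 142))
  expect_error(nox_total(-1, 5), "nonnegative")
  expect_equal(nox_total(0, 0), 0)
})

test_that("NO/NOx ratios reproduce reported values and behave monotonically", {
  tab <- site_nox_summary()
  expect_equal(tab$ratio_1dp[tab$site_id == 12], 0.8)
  expect_equal(tab$ratio_1dp[tab$site_id == 8], 0.8)
  expect_gt(min(tab$ratio), 0.5)
  expect_true(all(tab$ratio > 0 & tab$ratio <= 1))
  # strictly decreasing in NO2 at fixed NO; pure NO gives 1
  r <- vapply(seq(0, 50, by = 10), function(x) no_nox_ratio(100, x),
              numeric(1))
  expect_true(all(diff(r) < 0))
  expect_equal(no_nox_ratio(100, 0), 1)
  expect_error(no_nox_ratio(0, 0), "undefined")
})

test_that("ppb conversion derives the standard factors from the gas law", {
  expect_equal(round(ppb_to_ugm3(1, "NO"), 2), 1.25)
  expect_equal(round(ppb_to_ugm3(1, "NO2"), 2), 1.91)
  expect_equal(ppb_to_ugm3(0, "NO"), 0)
  # linear in value, inversely proportional to absolute temperature
  expect_equal(ppb_to_ugm3(10, "NO"), 10 * ppb_to_ugm3(1, "NO"))
  expect_equal(ppb_to_ugm3(1, "NO", temperature_c = 20) * (273.15 + 20),
               ppb_to_ugm3(1, "NO", temperature_c = 0) * 273.15)
  expect_error(ppb_to_ugm3(-1, "NO"), ">= 0")
  expect_error(ppb_to_ugm3(1, "SO2"), "arg")
})

test_that("diurnal profiles bin by local hour and ignore day order", {
  n <- 3 * 24
  g <- t_at("2023-10-21 00:00:00") + 3600 * (seq_len(n) - 1)
  flat <- diurnal_profile(nox_ts(g, rep(3, n), cadence = "hour"))
  expect_equal(nrow(flat), 24L)
  expect_equal(flat$mean, rep(3, 24))
  expect_equal(flat$n, rep(3L, 24))
  # shuffling whole day blocks leaves the profile unchanged
  set.seed(6)
  v <- rlnorm(n, 3, 0.5)
  prof <- diurnal_profile(nox_ts(g, v, cadence = "hour"))
  days <- sample(3)
  shuffled <- as.vector(matrix(v, nrow = 24)[, days])
  prof2 <- diurnal_profile(nox_ts(g, shuffled, cadence = "hour"))
  expect_equal(prof$mean, prof2$mean)
  expect_error(diurnal_profile(nox_ts(minute_grid(60), 1:60)), "hourly")
})

test_that("network diurnal NO peaks in the early morning", {
  cfg <- scenario_config(n_days = 7, sites = default_sites()[c(5, 8, 13), ],
                         seed = 47)
  net <- generate_network(cfg)
  hh <- lapply(cfg$sites$site_id, function(s)
    hourly_aggregate(bundle_ts(net, s, "NO", "total")))
  pooled <- nox_ts(hh[[1]]$time, rowMeans(sapply(hh, `[[`, "value")),
                   "net", "NO", "hour")
  prof <- diurnal_profile(pooled)
  expect_true(prof$hour[which.max(prof$mean)] %in% 5:7)
})

test_that("zone pooling is convex and respects one-site degeneracy", {
  meta <- site_meta(c("a", "b", "c"), c("OA", "OA", "SR"), "PCT2")
  set.seed(51)
  d <- data.frame(site_id = rep(c("a", "b", "c"), each = 100),
                  value = c(rlnorm(100, 4), rlnorm(100, 3), rlnorm(100, 2)))
  z <- zone_average(d, meta, "OA")
  site_means <- tapply(d$value[d$site_id != "c"], d$site_id[d$site_id != "c"],
                       mean)
  expect_gte(z$mean, min(site_means))
  expect_lte(z$mean, max(site_means))
  # single-site zone equals that site's stats
  zs <- zone_average(d, meta, "SR")
  expect_equal(as.data.frame(zs),
               as.data.frame(descriptive_stats(d$value[d$site_id == "c"])))
  # mean-of-site-means mode
  zm <- zone_average(d, meta, "OA", mode = "site_means")
  expect_equal(zm$mean, mean(site_means))
  expect_error(zone_average(d, meta, "BA"), "no sites")
})

test_that("site statistics tables cover every site/pollutant pair", {
  cfg <- scenario_config(n_days = 2, sites = default_sites()[1:3, ],
                         seed = 61)
  net <- generate_network(cfg)
  tab <- site_stats_table(net)
  expect_equal(nrow(tab), 6L)                  # 3 sites x 2 pollutants
  expect_setequal(unique(tab$pollutant), c("NO", "NO2"))
  one <- tab[tab$site_id == "1" & tab$pollutant == "NO", ]
  direct <- descriptive_stats(bundle_ts(net, "1", "NO", "total"))
  expect_equal(one$mean, direct$mean)
  expect_equal(one$p75, direct$p75)
})

test_that("zone NOx ordering matches emission intensity ordering", {
  sites <- site_meta(c("oa1", "oa2", "sr1", "ba1", "or1"),
                     c("OA", "OA", "SR", "BA", "OR"), "PCT4")
  cfg <- scenario_config(n_days = 6, sites = sites, seed = 53)
  net <- generate_network(cfg)
  nox <- vapply(c("OA", "SR", "BA", "OR"), function(z) {
    no <- zone_average(data.frame(
      site_id = net$data$site_id[net$data$pollutant == "NO"],
      value = net$data$total[net$data$pollutant == "NO"]), sites, z)$mean
    no2 <- zone_average(data.frame(
      site_id = net$data$site_id[net$data$pollutant == "NO2"],
      value = net$data$total[net$data$pollutant == "NO2"]), sites, z)$mean
    nox_total(no, no2)
  }, numeric(1))
  expect_true(all(diff(nox) < 0))
})
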