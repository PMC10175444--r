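test_that("canopy flux is the pointwise ecosystem minus floor difference", {
  eco <- make_flux_series(c(-20, -10, NA))
  fl <- make_flux_series(c(-5, 0, -2))
  can <- canopy_by_difference(eco, fl)
  expect_equal(can$flux, c(-15, -10, NA))
  expect_identical(can$qc_flag[3], "missing")
  # floor = 0 leaves the ecosystem flux unchanged
  zero_floor <- make_flux_series(rep(0, 3))
  expect_equal(canopy_by_difference(eco, zero_floor)$flux, eco$flux)
  # annual compartment arithmetic as published: eco -13.4 with a floor
  # source of +0.93 implies canopy deposition of 14.3 (1-decimal rounding)
  expect_equal(round(-13.4 - 0.93, 1), -14.3)
  expect_error(canopy_by_difference(eco, fl[1:2, ]), "grid")
})

test_that("day/night totals close exactly and respect the PAR threshold", {
  withr::with_seed(8, {
    n <- 96
    s <- make_flux_series(rep(-10, n))
    par <- rep(c(0, 600), each = n / 2)
    split <- day_night_split(s, par)
    expect_equal(split$day_total, split$night_total)
    expect_equal(split$day_total + split$night_total, split$total)
    expect_equal(split$total, sum(s$flux) * 0.5 / 1000)
    # all-dark series contributes nothing to the daytime total
    dark <- day_night_split(s, rep(0, n))
    expect_identical(dark$day_total, 0)
    expect_equal(dark$night_total, dark$total)
  })
})

test_that("missing PAR falls back to solar elevation and is counted", {
  s <- make_flux_series(rep(-10, 48), start = "2021-06-15 00:00")
  par <- rep(NA_real_, 48)
  split <- day_night_split(s, par, latitude = 45)
  expect_identical(split$n_par_fallback, 48L)
  expect_gt(split$day_total / split$total, 0.4)  # mid-June: long days
  expect_lt(split$day_total / split$total, 0.8)
})

test_that("cumulative flux integrates 30-min records into ug m-2", {
  n <- 365 * 48
  s <- make_flux_series(rep(-10, n), start = "2021-01-01 00:00")
  out <- cumulative_flux(s)
  expect_equal(out$total, -87.6)   # 10 ng/hr * 8760 hr / 1000
  expect_equal(cumulative_flux(make_flux_series(rep(0, 48)))$total, 0)
  s$flux[100] <- NA
  expect_error(cumulative_flux(s), "unfilled gap")
})

test_that("months observed twice are averaged before the annual sum", {
  # 13-month record: Jan 2021 at -10 and Jan 2022 at -30 must enter as
  # their average; other months at -10
  n21 <- as.integer(as.Date("2022-01-01") - as.Date("2021-01-01")) * 48
  n22 <- 31 * 48
  s <- make_flux_series(c(rep(-10, n21), rep(-30, n22)),
                        start = "2021-01-01 00:00")
  out <- cumulative_flux(s)
  jan_mean <- (-10 * 31 * 24 - 30 * 31 * 24) / 2 / 1000
  rest <- -10 * (8760 - 31 * 24) / 1000
  expect_equal(out$total, jan_mean + rest)
  # explicit annualize = FALSE gives the raw 13-month sum
  raw <- cumulative_flux(s, annualize = FALSE)
  expect_equal(raw$total, sum(s$flux) * 0.5 / 1000)
})

test_that("cumulative sums are additive over compartments and periods", {
  cfg <- scenario_config("deciduous", start = "2021-04-01",
                         end = "2021-09-30", seed = 4)
  met <- simulate_met(cfg)
  tr <- true_flux_field(cfg, met)
  eco <- make_flux_series(tr$ecosystem, start = "2021-04-01 00:00")
  fl <- make_flux_series(tr$floor, start = "2021-04-01 00:00")
  can <- make_flux_series(tr$canopy, start = "2021-04-01 00:00")
  expect_equal(cumulative_flux(eco)$total,
               cumulative_flux(fl)$total + cumulative_flux(can)$total,
               tolerance = 1e-6)
  # nested periods: [a,b] + [b,c] = [a,c]
  cut <- nrow(eco) %/% 2
  expect_equal(cumulative_flux(eco[1:cut, ])$total +
                 cumulative_flux(eco[(cut + 1):nrow(eco), ])$total,
               cumulative_flux(eco)$total, tolerance = 1e-9)
})

test_that("aggregation produces daily means and monthly medians", {
  s <- make_flux_series(rep(-10, 48), start = "2021-05-01 00:00")
  daily <- aggregate_fluxes(s, "daily_mean")
  expect_equal(nrow(daily), 1)
  expect_equal(daily$flux, -10)

  vals <- rep(c(-1, -2, -9), length.out = 31 * 48)
  s2 <- make_flux_series(vals, start = "2021-05-01 00:00")
  monthly <- aggregate_fluxes(s2, "monthly_median")
  expect_equal(monthly$flux, median(vals))

  # generator round trip: a configured mean emission is recovered in the
  # monthly statistic
  s3 <- make_flux_series(rep(7.2, 31 * 48), start = "2021-05-01 00:00")
  expect_equal(aggregate_fluxes(s3, "monthly_median")$flux, 7.2)
})

test_that("season labels follow the configured calendar window", {
  ts <- as.POSIXct(c("2021-03-15 12:00", "2021-04-01 00:00",
                     "2021-10-31 23:30", "2021-11-01 00:00"), tz = "UTC")
  expect_identical(season_label(ts, 4:10),
                   c("non_growing", "growing", "growing", "non_growing"))
  expect_identical(season_label(ts, 6:10)[2], "non_growing")
})
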