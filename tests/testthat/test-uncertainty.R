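make_paired_series <- function(n_days, flux_fn, noise = 0,
                               seed = 1) {
  withr::with_seed(seed, {
    n <- n_days * 48
    ts <- ts30(n, "2021-06-01 00:00")
    hour <- lubridate::hour(ts) + lubridate::minute(ts) / 60
    base <- flux_fn(hour)
    tibble::tibble(
      timestamp = ts,
      flux = base + if (noise > 0) rlaplace_oracle(n, noise) else 0,
      qc_flag = "ok", source = "measured",
      par = ifelse(hour >= 6 & hour < 18, 800, 0),
      ustar = 0.4
    )
  })
}

test_that("identical repeated days give all-zero daily differences", {
  s <- make_paired_series(10, function(h) -10 - 5 * sin(h / 24 * 2 * pi))
  p <- daily_difference_pairs(s)
  expect_equal(nrow(p), 9 * 48)
  expect_true(all(p$diff == 0))
  m <- fit_error_model(p)
  expect_identical(m$scale_beta, 0)
})

test_that("gap-filled records are excluded from pairing", {
  s <- make_paired_series(4, function(h) -10)
  s$source[49:96] <- "gap_fill"   # second day entirely imputed
  p <- daily_difference_pairs(s)
  # day1-day2 and day2-day3 pairs both involve the imputed day
  expect_equal(nrow(p), 48)
  expect_error(daily_difference_pairs(s[1:96, ]), "No acceptable")
})

test_that("pairs outside met tolerances are rejected", {
  s <- make_paired_series(2, function(h) -10)
  # daytime PAR of day 2 shifted beyond the 75-unit tolerance
  shift <- s$par > 0 & dplyr::row_number(s$timestamp) > 48
  s$par[shift] <- s$par[shift] + 100
  p <- daily_difference_pairs(s)
  expect_equal(nrow(p), 24)               # only the night half survives
  s$ustar[49:96] <- s$ustar[49:96] + 0.2  # and now u* breaks too
  expect_error(daily_difference_pairs(s), "No acceptable")
})

test_that("the Laplace scale is recovered from paired noise", {
  withr::with_seed(99, {
    d <- rlaplace_oracle(2e4, 5) - rlaplace_oracle(2e4, 5)
    m <- fit_error_model(d)
    expect_equal(m$scale_beta, 5, tolerance = 0.05)
    expect_equal(m$sigma, m$scale_beta * sqrt(2))
    # homogeneity: scaling the differences scales the estimate
    m3 <- fit_error_model(3 * d)
    expect_equal(m3$scale_beta, 3 * m$scale_beta, tolerance = 1e-12)
  })
})

test_that("tiny samples trigger the wide-uncertainty fallback", {
  withr::with_seed(2, {
    d <- rlaplace_oracle(10, 5) - rlaplace_oracle(10, 5)
    expect_warning(m <- fit_error_model(d), "fallback")
    expect_true(m$wide_fallback)
    expect_equal(m$scale_beta,
                 mean(abs(d - median(d))) / 1.5 * 2)
  })
})

test_that("tidy and glance expose the fitted error model", {
  m <- suppressWarnings(fit_error_model(c(-1, 0, 1)))
  td <- generics::tidy(m)
  expect_identical(td$term, c("scale_beta", "sigma"))
  gl <- generics::glance(m)
  expect_identical(gl$distribution, "laplace")
  expect_identical(gl$n_pairs, 3L)
})

test_that("propagation is deterministic, collapses at beta 0, guards draws", {
  s <- make_paired_series(30, function(h) -10)
  m <- fit_error_model(daily_difference_pairs(s))
  m$scale_beta <- 4
  a <- propagate_cumulative(s, m, n_draws = 200, seed = 42)
  b <- propagate_cumulative(s, m, n_draws = 200, seed = 42)
  expect_identical(a, b)
  c2 <- propagate_cumulative(s, m, n_draws = 200, seed = 43)
  expect_false(identical(a$lo, c2$lo))

  m0 <- m; m0$scale_beta <- 0
  z <- propagate_cumulative(s, m0, n_draws = 200, seed = 1)
  expect_equal(z$lo, z$total)
  expect_equal(z$hi, z$total)
  expect_error(propagate_cumulative(s, m, n_draws = 50), "at least 100")
})

test_that("interval width grows as sqrt(N) in the record count", {
  m <- structure(list(distribution = "laplace", scale_beta = 6,
                      sigma = 6 * sqrt(2), n_pairs = 1000,
                      wide_fallback = FALSE), class = "gem_error_model")
  s1 <- make_flux_series(rep(-10, 20 * 48))
  s4 <- make_flux_series(rep(-10, 80 * 48))
  w1 <- propagate_cumulative(s1, m, n_draws = 2000, seed = 5)$half_width
  w4 <- propagate_cumulative(s4, m, n_draws = 2000, seed = 5)$half_width
  expect_equal(w4 / w1, 2, tolerance = 0.1)
})

test_that("gap-filled records propagate with an inflated error scale", {
  m <- structure(list(distribution = "laplace", scale_beta = 6,
                      sigma = 6 * sqrt(2), n_pairs = 1000,
                      wide_fallback = FALSE), class = "gem_error_model")
  s <- make_flux_series(rep(-10, 40 * 48))
  s_gap <- s; s_gap$source <- "gap_fill"
  w_meas <- propagate_cumulative(s, m, n_draws = 2000, seed = 9)$half_width
  w_gap <- propagate_cumulative(s_gap, m, n_draws = 2000,
                                seed = 9)$half_width
  expect_equal(w_gap / w_meas, 2, tolerance = 0.05)
})
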