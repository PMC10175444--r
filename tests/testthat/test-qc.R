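test_that("trap-wise averaging means per trap before averaging gradients", {
  raw <- make_window_samples(c(A_upper = 1.04, A_lower = 1.00,
                               B_upper = 1.06, B_lower = 1.00))
  out <- trap_average(raw)
  expect_equal(nrow(out), 1)
  expect_equal(out$gradient, 0.05)   # mean of per-trap 0.04 and 0.06
  expect_equal(out$n_traps, 2L)
  expect_identical(out$grad_flag, "ok")
})

test_that("single-trap windows are used but flagged; empty heights missing", {
  one_trap <- make_window_samples(c(A_upper = 1.04, A_lower = 1.00))
  out <- trap_average(one_trap)
  expect_equal(out$gradient, 0.04)
  expect_identical(out$grad_flag, "single_trap")

  no_lower <- make_window_samples(c(A_upper = 1.04, B_upper = 1.06))
  out2 <- trap_average(no_lower)
  expect_true(is.na(out2$gradient))
  expect_identical(out2$grad_flag, "missing")
  expect_error(trap_average(dplyr::mutate(one_trap, conc = -conc)),
               "non-negative")
})

test_that("trap averaging cancels per-trap offsets where pooling cannot", {
  # unbalanced trap-height crossing: upper mostly trap A, lower mostly B
  delta <- 0.05
  raw <- make_window_samples(c(
    A_upper = 1.05 + delta, A_upper = 1.05 + delta, A_upper = 1.05 + delta,
    B_upper = 1.05 - delta,
    A_lower = 1.00 + delta,
    B_lower = 1.00 - delta, B_lower = 1.00 - delta, B_lower = 1.00 - delta
  ))
  out <- trap_average(raw)
  expect_equal(out$gradient, 0.05)   # true gradient, offsets cancelled
  # brute-force pooled estimate over all samples at each height is biased
  pooled <- mean(raw$conc[raw$height == "upper"]) -
    mean(raw$conc[raw$height == "lower"])
  expect_equal(pooled, 0.10)
  expect_gt(abs(pooled - 0.05), 0.04)
})

test_that("stability screen removes strictly outside [-2, 1] only", {
  s <- make_flux_series(rep(-10, 5))
  s$zeta <- c(-2.5, 0, 1.5, -2, 1)
  out <- stability_filter(s, qc_config())
  expect_identical(out$qc_flag,
                   c("stability_rejected", "ok", "stability_rejected",
                     "ok", "ok"))
  expect_identical(is.na(out$flux), c(TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("stability rejection fraction matches direct counting", {
  withr::with_seed(11, {
    n <- 5000
    s <- make_flux_series(rnorm(n, -5, 2))
    s$zeta <- runif(n, -3, 2)
    out <- stability_filter(s, qc_config())
    rejected <- sum(out$qc_flag == "stability_rejected")
    expect_identical(rejected, sum(s$zeta < -2 | s$zeta > 1))
    expect_equal(rejected / n, 2 / 5, tolerance = 0.05)
  })
})

test_that("robust outlier screen removes an injected spike and only it", {
  withr::with_seed(3, {
    s <- make_flux_series(c(rnorm(99), 50))
    out <- outlier_filter(s, "flux")
    expect_identical(which(out$qc_flag == "outlier_rejected"), 100L)
    # idempotent on its own output
    again <- outlier_filter(out, "flux")
    expect_identical(again$flux, out$flux)
    expect_identical(again$qc_flag, out$qc_flag)
  })
})

test_that("outlier screen is inert on degenerate (zero-MAD) series", {
  s <- make_flux_series(rep(-7, 50))
  out <- outlier_filter(s, "flux")
  expect_identical(out$flux, s$flux)
  expect_false(any(out$qc_flag == "outlier_rejected"))
})

test_that("gap filling uses the month-by-hour median and reports misses", {
  flux <- rep(NA_real_, 48 * 4)
  s <- make_flux_series(flux, start = "2021-07-01 00:00")
  hr13 <- lubridate::hour(s$timestamp) == 13
  s$flux[which(hr13)[1:3]] <- c(-10, -20, -30)
  s$qc_flag <- ifelse(is.na(s$flux), "missing", "ok")
  target <- which(hr13)[4]
  expect_warning(out <- gap_fill(s), "unfilled")
  expect_equal(out$flux[target], -20)
  expect_identical(out$qc_flag[target], "gap_filled")
  expect_identical(out$source[target], "gap_fill")
  # hours with no measured value in the cell stay missing
  expect_true(any(is.na(out$flux)))
})

test_that("gap filling never alters measured records; complete = no-op", {
  withr::with_seed(5, {
    s <- make_flux_series(rnorm(200, -5, 3))
    out <- gap_fill(s)
    expect_identical(out$flux, s$flux)
    expect_identical(out$source, s$source)

    s2 <- s
    s2$flux[c(10, 50)] <- NA
    s2$qc_flag[c(10, 50)] <- "missing"
    out2 <- gap_fill(s2)
    measured <- s2$source == "measured" & !is.na(s2$flux)
    expect_identical(out2$flux[measured], s2$flux[measured])
    expect_false(any(is.na(out2$flux)))
  })
})

test_that("pipeline flag accounting sums to the series length", {
  cfg <- scenario_config("coniferous", start = "2021-06-01",
                         end = "2021-07-31", seed = 21)
  sc <- simulate_scenario(cfg, compartments = "ecosystem")
  series <- suppressWarnings(
    process_fluxes(sc$samples_ecosystem, sc$met_ecosystem,
                   cfg$site_ecosystem)
  )
  counts <- qc_summary(series)
  expect_setequal(counts$qc_flag,
                  c("ok", "stability_rejected", "outlier_rejected",
                    "gap_filled", "missing"))
  expect_identical(sum(counts$n), nrow(series))
  expect_gt(counts$n[counts$qc_flag == "ok"], 0.6 * nrow(series))
})

test_that("qc thresholds are validated", {
  expect_error(qc_config(zeta_min = 2, zeta_max = 1))
  expect_error(qc_config(outlier_mad_threshold = 0))
})
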