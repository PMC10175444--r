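# shared fixture builders; everything is generated in code at test time

ts30 <- function(n, start = "2021-06-01 00:00") {
  seq(as.POSIXct(start, tz = "UTC"), by = "30 min", length.out = n)
}

# a minimal processed flux series on a 30-min grid
make_flux_series <- function(flux, start = "2021-06-01 00:00",
                             source = "measured") {
  tibble::tibble(
    timestamp = ts30(length(flux), start),
    flux = flux,
    qc_flag = ifelse(is.na(flux), "missing", "ok"),
    source = source
  )
}

# 5-min raw samples for one 30-min window with explicit per-trap
# concentrations; conc_by gives named values, e.g.
# c(A_upper = 1.04, A_lower = 1.00, B_upper = 1.06, B_lower = 1.00)
make_window_samples <- function(conc_by,
                                start = "2021-06-01 10:00",
                                reps = 1) {
  keys <- names(conc_by)
  parts <- strsplit(keys, "_")
  n_each <- length(keys) * reps
  tibble::tibble(
    timestamp = rep(as.POSIXct(start, tz = "UTC"), n_each) +
      300 * (seq_len(n_each) - 1) %% 6,
    conc = rep(unname(conc_by), each = reps),
    trap_id = rep(vapply(parts, `[`, "", 1), each = reps),
    height = rep(vapply(parts, `[`, "", 2), each = reps)
  )
}

# independent Laplace sampler for oracle checks (difference of two
# exponentials with the same scale)
rlaplace_oracle <- function(n, scale) {
  stats::rexp(n, rate = 1 / scale) - stats::rexp(n, rate = 1 / scale)
}

# hand-evaluated neutral gradient flux closed form (the test oracle)
neutral_flux_oracle <- function(ustar, dC, z2, z1, d, k = 0.4) {
  -ustar * k * dC / log((z2 - d) / (z1 - d)) * 3600
}
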