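#' Quality-control configuration
#'
#' Thresholds used along the data-quality chain for gradient fluxes:
#' the stability acceptance window on z/L, and the robust
#' median/MAD outlier threshold applied once to 30-min concentration
#' gradients and once to computed fluxes.
#'
#' The stability window is the closed interval `[zeta_min, zeta_max]`:
#' data are removed only when conditions are highly stable or unstable,
#' i.e. strictly `z/L < zeta_min` or `z/L > zeta_max`, so the boundary
#' values themselves are retained.
#'
#' @param zeta_min,zeta_max Stability acceptance bounds on z/L
#'   (defaults -2 and 1).
#' @param outlier_mad_threshold Records with
#'   `|x - median| / mad(x) > threshold` are rejected (default 3.5; `mad()`
#'   carries the usual 1.4826 consistency constant).
#' @param gapfill_window Gap-fill cell definition; only
#'   `"month_hour_median"` (median of the same calendar month and
#'   hour-of-day, years kept separate) is implemented.
#' @return A `gem_qc_config` list.
#' @export
qc_config <- function(zeta_min = -2, zeta_max = 1,
                      outlier_mad_threshold = 3.5,
                      gapfill_window = "month_hour_median") {
  stopifnot(zeta_min < zeta_max, outlier_mad_threshold > 0)
  gapfill_window <- match.arg(gapfill_window)
  structure(list(zeta_min = zeta_min, zeta_max = zeta_max,
                 outlier_mad_threshold = outlier_mad_threshold,
                 gapfill_window = gapfill_window),
            class = "gem_qc_config")
}

#' Trap-wise 30-min averaging of raw 5-min concentration samples
#'
#' Mercury vapour analyzers collect on two alternating gold traps; small
#' calibration offsets between traps bias a pooled gradient whenever trap
#' and inlet height are unevenly crossed within a window. Averaging is
#' therefore trap-wise: within each 30-min window, samples are averaged
#' per trap at each height, each trap's gradient (upper minus lower) is
#' formed, and the per-trap gradients are averaged. A window where only
#' one trap spans both heights uses that trap alone and is flagged
#' `single_trap`; a window missing a height entirely yields a missing
#' gradient.
#'
#' @param raw Data frame of 5-min samples with columns `timestamp`,
#'   `conc` (ng m-3 for GEM), `height` (`"upper"` or `"lower"`), and
#'   `trap_id` (`"A"`/`"B"`).
#' @return Tibble with one row per 30-min window: `timestamp` (window
#'   start), `c_upper`, `c_lower` (means of per-trap height means),
#'   `gradient` (mean of per-trap gradients), `n_traps`, and `grad_flag`
#'   (`"ok"`, `"single_trap"`, or `"missing"`).
#' @export
trap_average <- function(raw) {
  raw <- as_tibble(raw)
  stopifnot(all(c("timestamp", "conc", "height", "trap_id") %in% names(raw)))
  if (!all(raw$height %in% c("upper", "lower"))) {
    abort("`height` must be \"upper\" or \"lower\".")
  }
  if (any(raw$conc < 0, na.rm = TRUE)) {
    abort("Concentrations must be non-negative.")
  }
  raw <- raw[!is.na(raw$conc), , drop = FALSE]
  win <- lubridate::floor_date(raw$timestamp, "30 minutes")
  uw <- sort(unique(win))
  # encode (window, trap, height) as one integer key for fast group means
  code <- (match(win, uw) - 1L) * 4L + (raw$trap_id == "B") * 2L +
    (raw$height == "lower") + 1L
  sums <- rowsum(raw$conc, code)
  cnts <- rowsum(rep(1, length(code)), code)
  cells <- rep(NA_real_, length(uw) * 4L)
  cells[as.integer(rownames(sums))] <- sums / cnts
  m <- matrix(cells, ncol = 4L, byrow = TRUE)  # A-up, A-lo, B-up, B-lo
  grad_a <- m[, 1] - m[, 2]
  grad_b <- m[, 3] - m[, 4]
  n_traps <- (!is.na(grad_a)) + (!is.na(grad_b))
  nan_na <- function(x) ifelse(is.nan(x), NA_real_, x)
  tibble(
    timestamp = uw,
    c_upper = nan_na(rowMeans(m[, c(1, 3), drop = FALSE], na.rm = TRUE)),
    c_lower = nan_na(rowMeans(m[, c(2, 4), drop = FALSE], na.rm = TRUE)),
    gradient = nan_na(rowMeans(cbind(grad_a, grad_b), na.rm = TRUE)),
    n_traps = as.integer(n_traps),
    grad_flag = case_when(
      n_traps >= 2 ~ "ok",
      n_traps == 1 ~ "single_trap",
      TRUE ~ "missing"
    )
  )
}

#' Reject records under strongly stable or unstable stratification
#'
#' Flux-gradient theory breaks down outside moderate stability; records
#' with `zeta < zeta_min` or `zeta > zeta_max` (default outside
#' `[-2, 1]`) have their flux removed and are flagged
#' `stability_rejected`. Boundary values are retained. Records with
#' missing `zeta` are flagged `missing`.
#'
#' @param data Tibble with `flux`, `zeta`, and `qc_flag` columns.
#' @param cfg A [qc_config()].
#' @return `data` with `flux`/`qc_flag` updated.
#' @export
stability_filter <- function(data, cfg = qc_config()) {
  stopifnot(inherits(cfg, "gem_qc_config"))
  reject <- !is.na(data$zeta) &
    (data$zeta < cfg$zeta_min | data$zeta > cfg$zeta_max)
  data$flux[reject] <- NA_real_
  data$qc_flag[reject] <- "stability_rejected"
  no_zeta <- is.na(data$zeta) & data$qc_flag == "ok"
  data$flux[no_zeta] <- NA_real_
  data$qc_flag[no_zeta] <- "missing"
  data
}

# logical mask of robust MAD outliers; MAD = 0 or all-NA -> none removed
mad_outliers <- function(x, threshold) {
  m <- median(x, na.rm = TRUE)
  s <- mad(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  !is.na(x) & abs(x - m) / s > threshold
}

#' Robust outlier screening of a gradient or flux series
#'
#' Flags values whose distance from the series median exceeds
#' `threshold` robust standard deviations (`1.4826 * MAD`). Applied once
#' to 30-min concentration gradients and a second time to computed
#' fluxes. Idempotent on its own output; a degenerate series with zero
#' MAD is left untouched.
#'
#' @param data Tibble containing the target column and `qc_flag`.
#' @param var Name of the column to screen (default `"flux"`).
#' @param cfg A [qc_config()]; `outlier_mad_threshold` is used.
#' @param by `NULL` for one global screen, or `"month_hour"` to screen
#'   within calendar-month-by-hour-of-day cells so that diel and
#'   seasonal structure is not mistaken for spikes (requires a
#'   `timestamp` column; this is what [process_fluxes()] uses).
#' @return `data` with outliers set `NA` and flagged `outlier_rejected`.
#' @export
outlier_filter <- function(data, var = "flux", cfg = qc_config(),
                           by = NULL) {
  stopifnot(inherits(cfg, "gem_qc_config"), var %in% names(data))
  x <- data[[var]]
  if (is.null(by)) {
    out <- mad_outliers(x, cfg$outlier_mad_threshold)
  } else {
    stopifnot(by == "month_hour", "timestamp" %in% names(data))
    cell <- month_hour_key(data$timestamp)
    out <- logical(length(x))
    for (cl in split(seq_along(x), cell)) {
      out[cl] <- mad_outliers(x[cl], cfg$outlier_mad_threshold)
    }
  }
  data[[var]][out] <- NA_real_
  if (!"qc_flag" %in% names(data)) data$qc_flag <- "ok"
  data$qc_flag[out] <- "outlier_rejected"
  data
}

#' Fill flux gaps with month-by-hour medians
#'
#' Each missing 30-min flux is replaced by the median of measured fluxes
#' sharing its calendar month (within the same year) and hour-of-day.
#' Filled records get `source = "gap_fill"` and `qc_flag = "gap_filled"`;
#' the pre-fill flag is kept in `orig_flag`. Measured values are never
#' altered. Gaps whose (month, hour) cell holds no measured value stay
#' missing, with a warning reporting the count.
#'
#' @param data Tibble with `timestamp`, `flux`, `qc_flag`, `source`.
#' @return `data` with gaps filled where possible.
#' @export
gap_fill <- function(data) {
  stopifnot(all(c("timestamp", "flux", "qc_flag", "source") %in% names(data)))
  cell <- as.character(month_hour_key(data$timestamp))
  measured <- data$source == "measured" & !is.na(data$flux)
  med <- tapply(data$flux[measured], cell[measured], median)
  fill <- is.na(data$flux)
  filled_value <- unname(med[cell])
  if (!"orig_flag" %in% names(data)) data$orig_flag <- data$qc_flag
  ok <- fill & !is.na(filled_value)
  data$orig_flag[ok] <- data$qc_flag[ok]
  data$flux[ok] <- filled_value[ok]
  data$qc_flag[ok] <- "gap_filled"
  data$source[ok] <- "gap_fill"
  unfilled <- sum(fill & is.na(filled_value))
  if (unfilled > 0) {
    warn(paste0(unfilled,
                " gap(s) left unfilled: no measured value in their",
                " (month, hour) cell."))
    data$qc_flag[fill & is.na(filled_value)] <- "missing"
  }
  data
}

#' Run the full QC chain from raw 5-min samples to gap-filled fluxes
#'
#' Fixed processing order: trap-wise averaging to 30-min gradients,
#' robust outlier screening of gradients, merge with micrometeorology,
#' stability screening, flux computation via [gradient_flux()], a second
#' outlier screening of fluxes, then month-by-hour median gap filling.
#'
#' @param raw 5-min samples as accepted by [trap_average()].
#' @param met 30-min micrometeorology with `timestamp`, `ustar`, `zeta`
#'   and optionally `par`, `nep_flux`.
#' @param site A [site_config()].
#' @param cfg A [qc_config()].
#' @param gas Passed to [gradient_flux()].
#' @return A 30-min flux tibble with `flux`, `qc_flag`, `source`,
#'   `orig_flag` plus the met covariates.
#' @export
process_fluxes <- function(raw, met, site, cfg = qc_config(),
                           gas = "gem") {
  grads <- trap_average(raw)
  grads$qc_flag <- if_else(is.na(grads$gradient), "missing", "ok")
  grads <- outlier_filter(grads, var = "gradient", cfg = cfg,
                          by = "month_hour")

  met <- as_tibble(met)
  # full 30-min grid of the met record; windows without samples are gaps
  joined <- left_join(met, grads, by = "timestamp")
  joined$qc_flag[is.na(joined$qc_flag)] <- "missing"

  computed <- gradient_flux(joined, site, gas = gas)
  # keep rejection provenance from the gradient stage
  computed$qc_flag <- if_else(joined$qc_flag != "ok",
                              joined$qc_flag, computed$qc_flag)
  computed$flux[computed$qc_flag != "ok"] <- NA_real_
  computed <- stability_filter(computed, cfg)
  computed <- outlier_filter(computed, var = "flux", cfg = cfg,
                             by = "month_hour")
  computed$source <- if_else(is.na(computed$flux), computed$source, "measured")
  gap_fill(computed)
}

#' Per-flag record counts of a flux series
#'
#' @param series A flux tibble with `qc_flag` (and optionally
#'   `timestamp` for the per-month breakdown).
#' @param by_month Also break counts down by calendar month.
#' @return Tibble of flag counts; counts always sum to `nrow(series)`.
#' @export
qc_summary <- function(series, by_month = FALSE) {
  flags <- c("ok", "stability_rejected", "outlier_rejected",
             "gap_filled", "missing")
  f <- factor(series$qc_flag, levels = flags)
  if (by_month) {
    ym <- format(series$timestamp, "%Y-%m")
    out <- as.data.frame(table(month = ym, qc_flag = f))
    return(as_tibble(out) %>% rename(n = "Freq"))
  }
  tibble(qc_flag = flags, n = as.integer(table(f)))
}

# numeric (year, month, hour) cell key; fast on long POSIXct vectors
month_hour_key <- function(timestamp) {
  (lubridate::year(timestamp) * 12 + lubridate::month(timestamp)) * 24 +
    lubridate::hour(timestamp)
}
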