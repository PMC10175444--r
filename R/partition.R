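#' Canopy fluxes as the ecosystem/forest-floor differential
#'
#' A second gradient system under the canopy measures the forest-floor
#' (soil + litter + ground vegetation) exchange directly; the canopy
#' contribution is the pointwise difference between the whole-ecosystem
#' and floor series on the shared 30-min grid.
#'
#' @param ecosystem,floor Flux tibbles (`timestamp`, `flux`, `qc_flag`,
#'   `source`) on identical 30-min grids.
#' @return Tibble with `timestamp`, `flux` (= ecosystem - floor, `NA`
#'   where either side is missing), `qc_flag`, and `source`
#'   (`"measured"` only when both sides are measured).
#' @export
canopy_by_difference <- function(ecosystem, floor) {
  ecosystem <- arrange(as_tibble(ecosystem), .data$timestamp)
  floor <- arrange(as_tibble(floor), .data$timestamp)
  if (nrow(ecosystem) != nrow(floor) ||
      !all(ecosystem$timestamp == floor$timestamp)) {
    abort("`ecosystem` and `floor` must share the same 30-min grid.")
  }
  flux <- ecosystem$flux - floor$flux
  tibble(
    timestamp = ecosystem$timestamp,
    flux = flux,
    qc_flag = if_else(is.na(flux), "missing", "ok"),
    source = if_else(ecosystem$source == "measured" &
                       floor$source == "measured",
                     "measured", "gap_fill")
  )
}

# day mask: PAR above threshold; solar-elevation fallback where PAR missing
day_mask <- function(timestamp, par, threshold = 5, latitude = 45) {
  mask <- par > threshold
  miss <- is.na(mask)
  if (any(miss)) {
    mask[miss] <- solar_elevation(timestamp[miss], latitude) > 0
  }
  list(mask = mask, n_fallback = sum(miss))
}

#' Split cumulative flux into daytime and nighttime contributions
#'
#' Records are daytime when photosynthetically active radiation exceeds
#' `threshold` (default 5 umol m-2 s-1); records with missing PAR fall
#' back to a positive solar elevation and are counted in `n_par_fallback`.
#' Totals are direct sums of 30-min fluxes converted to ug m-2.
#'
#' @param series Flux tibble (`timestamp`, `flux` in ng m-2 hr-1).
#' @param par PAR series aligned with `series` (umol m-2 s-1).
#' @param threshold Day/night PAR threshold (umol m-2 s-1).
#' @param latitude Site latitude (deg N) for the fallback.
#' @return One-row tibble: `day_total`, `night_total`, `total` (ug m-2),
#'   `n_par_fallback`.
#' @export
day_night_split <- function(series, par, threshold = 5, latitude = 45) {
  stopifnot(length(par) == nrow(series))
  dm <- day_mask(series$timestamp, par, threshold, latitude)
  to_ug <- function(x) sum(x, na.rm = TRUE) * 0.5 / 1000
  day_total <- to_ug(series$flux[dm$mask])
  night_total <- to_ug(series$flux[!dm$mask])
  tibble(day_total = day_total, night_total = night_total,
         total = day_total + night_total, n_par_fallback = dm$n_fallback)
}

#' Cumulative flux over a period, with annual normalization
#'
#' Direct sum of 30-min fluxes: `sum(flux [ng m-2 hr-1] * 0.5 hr) / 1000`
#' in ug m-2. For records longer than 12 months, calendar months observed
#' in more than one year are first averaged (the monthly totals are
#' averaged across years) so that the result is an annualized sum over
#' the 12 calendar months. Errors if the period still contains unfilled
#' gaps, listing the missing intervals.
#'
#' @param series Gap-filled flux tibble (`timestamp`, `flux`).
#' @param annualize Average doubly-observed calendar months before
#'   summing (default `TRUE` when the record spans more than 12 months).
#' @return One-row tibble: `total` (ug m-2), `n_records`, `start`, `end`.
#' @export
cumulative_flux <- function(series, annualize = NULL) {
  series <- arrange(as_tibble(series), .data$timestamp)
  gaps <- is.na(series$flux)
  if (any(gaps)) {
    where <- format(series$timestamp[gaps])
    show <- paste(utils::head(where, 5), collapse = ", ")
    abort(paste0(sum(gaps), " unfilled gap(s) in period (first: ",
                 show, "); gap-fill before accumulating."))
  }
  yr <- lubridate::year(series$timestamp)
  mo <- lubridate::month(series$timestamp)
  months_spanned <- length(unique(yr * 12 + mo))
  if (is.null(annualize)) annualize <- months_spanned > 12
  if (annualize) {
    monthly <- series %>%
      mutate(ym = .env$yr * 12 + .env$mo, mon = .env$mo) %>%
      group_by(.data$mon, .data$ym) %>%
      summarise(m_total = sum(.data$flux) * 0.5 / 1000, .groups = "drop") %>%
      group_by(.data$mon) %>%
      summarise(m_total = mean(.data$m_total), .groups = "drop")
    total <- sum(monthly$m_total)
  } else {
    total <- sum(series$flux) * 0.5 / 1000
  }
  tibble(total = total, n_records = nrow(series),
         start = min(series$timestamp), end = max(series$timestamp))
}

#' Daily means or monthly medians of a 30-min flux series
#'
#' @param series Flux tibble (`timestamp`, `flux`).
#' @param level `"daily_mean"` (arithmetic mean of each day's 30-min
#'   values) or `"monthly_median"` (median of each month's 30-min
#'   values). Units are preserved.
#' @return Tibble with `period` (Date or "YYYY-MM") and `flux`.
#' @export
aggregate_fluxes <- function(series, level = c("daily_mean",
                                               "monthly_median")) {
  level <- match.arg(level)
  series <- as_tibble(series)
  if (level == "daily_mean") {
    series %>%
      mutate(period = lubridate::as_date(.data$timestamp)) %>%
      group_by(.data$period) %>%
      summarise(flux = mean(.data$flux, na.rm = TRUE), .groups = "drop")
  } else {
    series %>%
      mutate(period = format(.data$timestamp, "%Y-%m")) %>%
      group_by(.data$period) %>%
      summarise(flux = median(.data$flux, na.rm = TRUE), .groups = "drop")
  }
}

#' Label records as growing or non-growing season
#'
#' Growing-season windows are configured calendar spans, not inferred
#' from phenology: deciduous forests June-October, coniferous forests
#' April-October by default.
#'
#' @param timestamp POSIXct vector.
#' @param months Integer months belonging to the growing season.
#' @return Character vector `"growing"` / `"non_growing"`.
#' @export
season_label <- function(timestamp, months = 4:10) {
  if_else(lubridate::month(timestamp) %in% months,
          "growing", "non_growing")
}
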