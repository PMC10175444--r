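#' End-to-end annual flux estimate from a synthetic or measured record
#'
#' Convenience wrapper chaining the whole inference: QC and gap filling
#' via [process_fluxes()], daily-differencing error estimation (fitted
#' separately for day and night records, since gradient-flux random
#' error scales with turbulence and is strongly diel), and Monte-Carlo
#' propagation into the annual cumulative flux.
#'
#' @param samples 5-min concentration samples ([trap_average()] format).
#' @param met 30-min met tibble (`timestamp`, `ustar`, `zeta`, `par`).
#' @param site The system's [site_config()].
#' @param cfg_qc A [qc_config()].
#' @param n_draws Monte-Carlo replicates for the interval.
#' @param seed Seed for the propagation.
#' @param par_threshold Day/night PAR threshold (umol m-2 s-1).
#' @return List with `series` (the processed flux tibble), `models`
#'   (day and night `gem_error_model`s) and `annual` (one-row tibble:
#'   `total`, `lo`, `hi`, `half_width`, ug m-2).
#' @export
estimate_annual_flux <- function(samples, met, site,
                                 cfg_qc = qc_config(),
                                 n_draws = 400, seed = 1L,
                                 par_threshold = 5) {
  series <- process_fluxes(samples, met, site, cfg = cfg_qc)
  pairs <- daily_difference_pairs(series)
  day_at <- series$par[match(pairs$timestamp, series$timestamp)] >
    par_threshold
  fit_or_null <- function(d) if (length(d) > 0) fit_error_model(d) else NULL
  m_day <- fit_or_null(pairs$diff[day_at])
  m_night <- fit_or_null(pairs$diff[!day_at])
  fallback <- fit_error_model(pairs$diff)
  if (is.null(m_day)) m_day <- fallback
  if (is.null(m_night)) m_night <- fallback
  is_day <- !is.na(series$par) & series$par > par_threshold
  scales <- if_else(is_day, m_day$scale_beta, m_night$scale_beta)
  annual <- propagate_cumulative(series, fallback, n_draws = n_draws,
                                 seed = seed, record_scales = scales)
  list(series = series, models = list(day = m_day, night = m_night),
       annual = annual)
}
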