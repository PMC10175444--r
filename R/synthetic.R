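#' Configure a synthetic forest GEM-exchange scenario
#'
#' Builds the configuration for a site-like half-hourly record: solar
#' geometry drives PAR, turbulence has a day/night contrast with
#' stability drawn unstable by day and stable by night, the canopy takes
#' up GEM through a rectangular-hyperbola light response coupled to the
#' CO2 assimilation proxy, the forest floor exchanges GEM with a
#' configurable sign, and observations are produced by inverting the
#' gradient equation into two-height 5-min trap-tagged concentration
#' samples with additive Laplace noise and missing windows.
#'
#' Two presets mirror the contrasting forest types: `"coniferous"`
#' (growing season April-October, nocturnal canopy deposition, the
#' forest floor a small source; annual ecosystem deposition of order
#' 13 ug m-2) and `"deciduous"` (growing season June-October, nocturnal
#' canopy emission, the floor a substantial sink; annual deposition of
#' order 25 ug m-2). Uptake coefficients were fixed once from the
#' light-response integral so the presets land on those annual totals.
#'
#' @param preset `"coniferous"` or `"deciduous"`.
#' @param start,end Date range (inclusive) of the record.
#' @param seed Integer seed; every generated quantity is a pure
#'   function of the configuration and this seed.
#' @param noise_scale_beta Laplace scale of per-5-min concentration
#'   noise (ng m-3).
#' @param gap_fraction Fraction of 30-min windows dropped at random.
#' @param trap_offset Half-difference of the two analyzer traps'
#'   calibration (ng m-3): trap A reads `+trap_offset`, trap B
#'   `-trap_offset`.
#' @param zeta_excursion_rate Probability that a record's z/L is drawn
#'   outside the acceptance window [-2, 1].
#' @param stomatal_uptake_coeff Canopy uptake at light/season saturation
#'   (ng m-2 hr-1).
#' @param nocturnal_canopy_flux Canopy flux added at night during the
#'   active season (ng m-2 hr-1; negative = deposition).
#' @param floor_flux_mean Mean forest-floor flux (ng m-2 hr-1).
#' @param background_conc Background GEM concentration (ng m-3).
#' @param latitude Site latitude (deg N).
#' @param growing_months Integer months of the active season.
#' @param site_ecosystem,site_floor [site_config()] objects.
#' @return A `gem_scenario_config` list.
#' @export
scenario_config <- function(preset = c("coniferous", "deciduous"),
                            start = "2021-01-01", end = "2021-12-31",
                            seed = 1L,
                            noise_scale_beta = 0.0012,
                            gap_fraction = 0.2,
                            trap_offset = 0.01,
                            zeta_excursion_rate = 0.03,
                            stomatal_uptake_coeff = NULL,
                            nocturnal_canopy_flux = NULL,
                            floor_flux_mean = NULL,
                            background_conc = NULL,
                            latitude = 45,
                            growing_months = NULL,
                            site_ecosystem = NULL,
                            site_floor = NULL) {
  preset <- match.arg(preset)
  stopifnot(gap_fraction >= 0, gap_fraction < 1,
            noise_scale_beta >= 0, zeta_excursion_rate >= 0)
  defaults <- if (preset == "coniferous") {
    list(stomatal_uptake_coeff = 11.9, nocturnal_canopy_flux = -0.7,
         floor_flux_mean = 0.106, background_conc = 1.03,
         nep_amax = 20, growing_months = 4:10,
         site_ecosystem = site_config(28.2, 23.2, canopy_height = 20,
                                      system_label = "ecosystem"),
         site_floor = site_config(2.6, 1.3, canopy_height = 0,
                                  system_label = "floor"))
  } else {
    list(stomatal_uptake_coeff = 21.4, nocturnal_canopy_flux = 0.73,
         floor_flux_mean = -1.107, background_conc = 1.10,
         nep_amax = 33.5, growing_months = 6:10,
         site_ecosystem = site_config(30.8, 24.1, canopy_height = 24,
                                      system_label = "ecosystem"),
         site_floor = site_config(1.2, 0.4, canopy_height = 0,
                                  system_label = "floor"))
  }
  pick <- function(x, d) if (is.null(x)) d else x
  structure(
    list(preset = preset,
         start = as.Date(start), end = as.Date(end),
         seed = as.integer(seed),
         noise_scale_beta = noise_scale_beta,
         gap_fraction = gap_fraction,
         trap_offset = trap_offset,
         zeta_excursion_rate = zeta_excursion_rate,
         stomatal_uptake_coeff = pick(stomatal_uptake_coeff,
                                      defaults$stomatal_uptake_coeff),
         nocturnal_canopy_flux = pick(nocturnal_canopy_flux,
                                      defaults$nocturnal_canopy_flux),
         floor_flux_mean = pick(floor_flux_mean, defaults$floor_flux_mean),
         background_conc = pick(background_conc, defaults$background_conc),
         latitude = latitude,
         nep_amax = defaults$nep_amax,
         growing_months = pick(growing_months, defaults$growing_months),
         site_ecosystem = pick(site_ecosystem, defaults$site_ecosystem),
         site_floor = pick(site_floor, defaults$site_floor)),
    class = "gem_scenario_config"
  )
}

# smooth seasonal activity 0..1 over the growing window
season_weight <- function(timestamp, growing_months) {
  doy <- lubridate::yday(timestamp)
  first <- min(growing_months)
  last <- max(growing_months)
  start_doy <- lubridate::yday(as.Date(sprintf("2021-%02d-01", first)))
  end_doy <- lubridate::yday(as.Date(sprintf("2021-%02d-28", last)))
  frac <- (doy - start_doy) / (end_doy - start_doy)
  ifelse(frac > 0 & frac < 1, sin(pi * frac)^0.7, 0)
}

#' Simulate half-hourly micrometeorology
#'
#' Generates the 30-min above-canopy met record: PAR from solar
#' elevation modulated by a random cloud factor, friction velocity with
#' a day/night contrast, stability z/L drawn unstable by day and stable
#' by night with occasional excursions beyond [-2, 1], and a CO2 flux
#' (NEP, negative = uptake) from the same light response that drives
#' canopy GEM uptake.
#'
#' @param cfg A [scenario_config()].
#' @return Tibble: `timestamp`, `par`, `ustar`, `zeta`, `nep_flux`.
#' @export
simulate_met <- function(cfg) {
  stopifnot(inherits(cfg, "gem_scenario_config"))
  ts <- seq(as.POSIXct(paste(cfg$start, "00:00"), tz = "UTC"),
            as.POSIXct(paste(cfg$end, "23:30"), tz = "UTC"),
            by = "30 min")
  n <- length(ts)
  withr::with_seed(cfg$seed, {
    elev <- solar_elevation(ts, cfg$latitude)
    cloud <- 1 - 0.7 * runif(n)^2
    par <- pmax(0, 1800 * sin(pmax(0, elev) * pi / 180)) * cloud
    day <- par > 5
    ustar <- ifelse(day, 0.45 + 0.25 * sin(pmax(0, elev) * pi / 180),
                    0.22) + abs(rnorm(n, 0, 0.08))
    zeta <- ifelse(day, -abs(rnorm(n, 0.3, 0.35)),
                   abs(rnorm(n, 0.25, 0.2)))
    exc <- runif(n) < cfg$zeta_excursion_rate
    zeta[exc] <- ifelse(day[exc], runif(sum(exc), -4, -2.05),
                        runif(sum(exc), 1.05, 3))
    s <- season_weight(ts, cfg$growing_months)
    assim <- par / (par + 500)
    nep <- -cfg$nep_amax * assim * s + (1.2 + 2.2 * s) + rnorm(n, 0, 0.4)
    tibble(timestamp = ts, par = par, ustar = ustar, zeta = zeta,
           nep_flux = nep)
  })
}

#' True GEM flux field per compartment
#'
#' Canopy uptake follows the PAR light response scaled by the seasonal
#' activity weight, plus the configured nocturnal canopy flux during the
#' active season; the forest floor carries the configured mean with a
#' small diel modulation; the ecosystem truth is their sum by
#' construction.
#'
#' @param cfg A [scenario_config()].
#' @param met Output of [simulate_met()].
#' @return Tibble: `timestamp`, `canopy`, `floor`, `ecosystem`
#'   (ng m-2 hr-1).
#' @export
true_flux_field <- function(cfg, met) {
  stopifnot(inherits(cfg, "gem_scenario_config"))
  s <- season_weight(met$timestamp, cfg$growing_months)
  assim <- met$par / (met$par + 500)
  night <- met$par <= 5
  canopy <- -cfg$stomatal_uptake_coeff * assim * s +
    cfg$nocturnal_canopy_flux * night * s
  hour <- lubridate::hour(met$timestamp) +
    lubridate::minute(met$timestamp) / 60
  floor <- cfg$floor_flux_mean *
    (1 + 0.3 * sin(2 * pi * (hour - 6) / 24))
  tibble(timestamp = met$timestamp, canopy = canopy, floor = floor,
         ecosystem = canopy + floor)
}

#' Invert the gradient equation into 5-min trap-tagged samples
#'
#' Forward model: for each 30-min record the concentration difference
#' that the gradient equation would produce from the true flux is
#' `c_upper - c_lower = -(F/3600) * D / (ustar * k)` with `D` the
#' stability-corrected log-profile denominator; the background
#' concentration is split symmetrically across the two inlets. Each
#' window is expanded to six 5-min samples with 10-min inlet switching
#' (heights alternate in pairs, the starting height alternating by
#' window) and the analyzer trap alternating every sample; per-trap
#' calibration offsets of `+/- trap_offset` and iid Laplace
#' concentration noise are added, and a `gap_fraction` share of windows
#' is dropped. Windows with `ustar = 0` or a non-positive denominator
#' have no defined gradient and yield no samples.
#'
#' @param truth Numeric vector of true fluxes (ng m-2 hr-1) aligned
#'   with `met`.
#' @param met 30-min met tibble (`timestamp`, `ustar`, `zeta`).
#' @param site The [site_config()] of the simulated system.
#' @param cfg A [scenario_config()].
#' @param seed Seed for noise, trap offsets and gaps (defaults to
#'   `cfg$seed`).
#' @return 5-min tibble: `timestamp`, `conc`, `height`, `trap_id`.
#' @export
fluxes_to_concentrations <- function(truth, met, site, cfg,
                                     seed = cfg$seed) {
  stopifnot(inherits(cfg, "gem_scenario_config"),
            inherits(site, "gem_site"), length(truth) == nrow(met))
  den <- stability_denominator(met$zeta, site)
  grad <- -(truth / 3600) * den / (met$ustar * site$von_karman)
  grad[is.na(den) | den <= 0 | is.na(met$ustar) | met$ustar == 0] <- NA_real_
  n <- nrow(met)
  withr::with_seed(seed, {
    keep <- runif(n) >= cfg$gap_fraction & !is.na(grad)
    idx <- rep(which(keep), each = 6)
    slot <- rep(0:5, times = sum(keep))
    win <- rep(seq_len(n)[keep], each = 6)
    # 10-min switching: heights in pairs, starting height alternates
    first_upper <- win %% 2 == 0
    in_first_pair <- slot %in% c(0, 1) | slot %in% c(4, 5)
    upper <- (first_upper & in_first_pair) | (!first_upper & !in_first_pair)
    trap <- ifelse((win * 6 + slot) %% 2 == 0, "A", "B")
    conc_true <- cfg$background_conc +
      ifelse(upper, grad[idx] / 2, -grad[idx] / 2)
    conc <- conc_true +
      ifelse(trap == "A", cfg$trap_offset, -cfg$trap_offset) +
      rlaplace(length(idx), cfg$noise_scale_beta)
    tibble(
      timestamp = met$timestamp[idx] + slot * 300,
      conc = pmax(conc, 0),
      height = ifelse(upper, "upper", "lower"),
      trap_id = trap
    )
  })
}

#' Generate a complete synthetic scenario
#'
#' Runs [simulate_met()], [true_flux_field()] and
#' [fluxes_to_concentrations()] for the ecosystem and (optionally)
#' forest-floor systems. The floor system's met is derived from the
#' above-canopy record with reduced friction velocity and damped
#' stability, as measured by an understory sonic.
#'
#' @param cfg A [scenario_config()].
#' @param compartments `"both"` or `"ecosystem"` only.
#' @return A `gem_scenario` list: `cfg`, `met_ecosystem`, `met_floor`,
#'   `truth`, `samples_ecosystem`, `samples_floor`.
#' @export
simulate_scenario <- function(cfg, compartments = c("both", "ecosystem")) {
  compartments <- match.arg(compartments)
  met <- simulate_met(cfg)
  truth <- true_flux_field(cfg, met)
  samples_eco <- fluxes_to_concentrations(truth$ecosystem, met,
                                          cfg$site_ecosystem, cfg,
                                          seed = cfg$seed + 1L)
  out <- list(cfg = cfg, met_ecosystem = met, truth = truth,
              samples_ecosystem = samples_eco)
  if (compartments == "both") {
    met_floor <- withr::with_seed(cfg$seed + 2L, {
      mutate(met,
             ustar = pmax(0.03, 0.35 * .data$ustar +
                            rnorm(nrow(met), 0, 0.01)),
             zeta = 0.5 * .data$zeta)
    })
    out$met_floor <- met_floor
    out$samples_floor <- fluxes_to_concentrations(truth$floor, met_floor,
                                                  cfg$site_floor, cfg,
                                                  seed = cfg$seed + 3L)
  }
  structure(out, class = "gem_scenario")
}
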