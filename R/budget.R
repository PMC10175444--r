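#' Published annual mercury deposition components for two forests
#'
#' Annual component fluxes (ug m-2 yr-1, negative = deposition) for a
#' deciduous forest (Harvard Forest, MA) and a coniferous forest
#' (Howland Forest, ME): direct GEM flux measurements, wet deposition,
#' Hg(II) and particulate dry deposition, and the litterfall /
#' throughfall / open-field proxies. The deciduous wet-deposition entry
#' is an interpolated-map estimate reported as "about 5"; it is stored
#' as exactly 5.0 and marked in `wet_approx`.
#'
#' @return Tibble, one row per site.
#' @export
forest_hg_budget <- function() {
  readr::read_csv(
    system.file("extdata", "forest_hg_budget.csv", package = "gemflux"),
    show_col_types = FALSE
  )
}

#' Published GEM deposition and NEP magnitudes across five ecosystems
#'
#' Growing-season and annual GEM deposition (ug m-2) and net ecosystem
#' productivity (g C m-2) for five biomes, together with the uptake
#' ratios as printed at 3-decimal rounding (for cross-checking
#' [hg_c_ratio()]). The tundra annual NEP is negative (net carbon
#' source), which carries through to a negative ratio.
#'
#' @return Tibble, one row per biome.
#' @export
hg_c_uptake_table <- function() {
  readr::read_csv(
    system.file("extdata", "hg_c_uptake_table.csv", package = "gemflux"),
    show_col_types = FALSE
  )
}

#' Hg:C uptake ratio
#'
#' Ratio of GEM deposition to net ecosystem productivity over a matching
#' period, in ug Hg per g C. The sign is carried through: a negative NEP
#' (net carbon source) with GEM deposition gives a negative ratio.
#'
#' @param gem GEM deposition magnitude (ug m-2).
#' @param nep Net ecosystem productivity (g C m-2); must be nonzero.
#' @param period Label, `"growing"` or `"annual"`.
#' @return Tibble with `gem`, `nep`, `period`, `ratio` (unrounded) and
#'   `ratio_3dp` (reporting value, 3 decimals).
#' @examples
#' hg_c_ratio(12.6, 224)$ratio_3dp  # 0.056
#' @export
hg_c_ratio <- function(gem, nep, period = "growing") {
  if (any(nep == 0)) abort("Hg:C ratio undefined where `nep` = 0.")
  ratio <- gem / nep
  tibble(gem = gem, nep = nep, period = period,
         ratio = ratio, ratio_3dp = round(ratio, 3))
}

budget_cols <- c("gem_annual", "wet", "hg2_dry", "phg_dry")

#' Total atmospheric mercury deposition and the GEM share
#'
#' Sums the four primary deposition pathways — net GEM exchange, wet
#' deposition, Hg(II) dry and particulate dry deposition — and reports
#' the GEM fraction of the total. Litterfall and throughfall are
#' proxies/sub-components and are deliberately not added. Components are
#' signed (negative = deposition); the GEM share is computed on
#' magnitudes.
#'
#' @param budget Data frame with columns `gem_annual`, `wet`, `hg2_dry`,
#'   `phg_dry` (ug m-2 yr-1, signed), e.g. [forest_hg_budget()].
#' @return `budget` with `total` (signed, ug m-2 yr-1),
#'   `gem_fraction_pct` (unrounded %) and `gem_fraction_pct_int`
#'   (reporting value, integer %) appended.
#' @examples
#' total_deposition(forest_hg_budget())
#' @export
total_deposition <- function(budget) {
  missing_cols <- setdiff(budget_cols, names(budget))
  if (length(missing_cols) > 0) {
    abort(paste("Missing component column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  for (col in budget_cols) {
    if (any(is.na(budget[[col]]))) {
      abort(paste0("Component `", col, "` has missing values."))
    }
  }
  budget <- as_tibble(budget)
  budget$total <- budget$gem_annual + budget$wet + budget$hg2_dry +
    budget$phg_dry
  budget$gem_fraction_pct <- abs(budget$gem_annual) / abs(budget$total) * 100
  budget$gem_fraction_pct_int <- round(budget$gem_fraction_pct)
  budget
}

#' Directly measured total dry deposition
#'
#' Sum of the three dry pathways: net GEM exchange, Hg(II) dry and
#' particulate dry deposition. Reported as a magnitude (ug m-2 yr-1).
#'
#' @inheritParams total_deposition
#' @return `budget` with `dry_direct` appended.
#' @export
dry_deposition_direct <- function(budget) {
  need <- c("gem_annual", "hg2_dry", "phg_dry")
  missing_cols <- setdiff(need, names(budget))
  if (length(missing_cols) > 0) {
    abort(paste("Missing component column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  budget <- as_tibble(budget)
  budget$dry_direct <- abs(budget$gem_annual) + abs(budget$hg2_dry) +
    abs(budget$phg_dry)
  budget
}

#' Litterfall + throughfall proxy for dry deposition
#'
#' In the absence of direct GEM flux measurements, dry deposition is
#' conventionally estimated as throughfall plus litterfall loadings
#' minus open-area (wet-only) loadings. Inputs are magnitudes; a
#' negative result is physically odd and flagged.
#'
#' @param litterfall,throughfall,open_field Deposition magnitudes
#'   (ug m-2 yr-1).
#' @return Tibble with `dry_proxy` and `negative_flag`.
#' @examples
#' dry_deposition_proxy(12.3, 7.0, 5.0)$dry_proxy  # 14.3
#' @export
dry_deposition_proxy <- function(litterfall, throughfall, open_field) {
  if (any(c(litterfall, throughfall, open_field) < 0)) {
    abort("Supply magnitudes (non-negative) to the proxy estimate.")
  }
  dry <- litterfall + throughfall - open_field
  tibble(litterfall = litterfall, throughfall = throughfall,
         open_field = open_field, dry_proxy = dry,
         negative_flag = dry < 0)
}

#' Wet/throughfall deposition from sample concentrations and water flux
#'
#' Deposition is the concentration-weighted water flux:
#' `sum(conc [ng L-1] * depth [mm]) / 1000` in ug m-2, using
#' 1 mm over 1 m2 = 1 L.
#'
#' @param samples Data frame with `conc_ng_l` and `depth_mm` columns
#'   (paired sample concentration and water depth).
#' @return One-row tibble: `deposition` (ug m-2), `total_depth_mm`,
#'   `n_samples`.
#' @examples
#' wet_deposition_from_samples(
#'   tibble::tibble(conc_ng_l = 4.3, depth_mm = 1186))
#' @export
wet_deposition_from_samples <- function(samples) {
  stopifnot(all(c("conc_ng_l", "depth_mm") %in% names(samples)))
  if (any(samples$conc_ng_l < 0 | samples$depth_mm < 0, na.rm = TRUE)) {
    abort("Concentrations and depths must be non-negative.")
  }
  tibble(
    deposition = sum(samples$conc_ng_l * samples$depth_mm,
                     na.rm = TRUE) / 1000,
    total_depth_mm = sum(samples$depth_mm, na.rm = TRUE),
    n_samples = sum(!is.na(samples$conc_ng_l) & !is.na(samples$depth_mm))
  )
}

#' Litterfall mercury deposition from foliar concentration and mass
#'
#' `conc [ng g-1] * mass [g m-2] / 1000` in ug m-2; both inputs are
#' user-supplied site data.
#'
#' @param foliar_conc_ng_g Foliar Hg concentration (ng g-1 dry weight).
#' @param litterfall_mass_g_m2 Annual litterfall mass (g m-2 yr-1).
#' @return Deposition (ug m-2 yr-1).
#' @export
litterfall_deposition <- function(foliar_conc_ng_g, litterfall_mass_g_m2) {
  stopifnot(foliar_conc_ng_g >= 0, litterfall_mass_g_m2 >= 0)
  foliar_conc_ng_g * litterfall_mass_g_m2 / 1000
}

#' Floor-to-canopy flux shares and canopy contrast
#'
#' Expresses each forest-floor flux as a percentage of the corresponding
#' canopy flux magnitude with a direction tag (same or opposite sign),
#' and the canopy-vs-canopy percent difference relative to the smaller
#' magnitude. Optionally reports the NEP contrast factor between the
#' two sites.
#'
#' @param canopy_a,canopy_b Canopy fluxes (signed, ug m-2 yr-1).
#' @param floor_a,floor_b Floor fluxes (signed, ug m-2 yr-1).
#' @param nep_a,nep_b Optional annual NEP (g C m-2 yr-1) for the
#'   contrast factor.
#' @return One-row tibble: `floor_share_a_pct`, `direction_a`,
#'   `floor_share_b_pct`, `direction_b`, `canopy_diff_pct`, and
#'   `nep_contrast` when NEP is supplied.
#' @examples
#' flux_ratio_report(-14.3, -15.4, 0.93, -9.7, nep_a = 197, nep_b = 416)
#' @export
flux_ratio_report <- function(canopy_a, canopy_b, floor_a, floor_b,
                              nep_a = NULL, nep_b = NULL) {
  if (canopy_a == 0 || canopy_b == 0) {
    abort("Floor-to-canopy share undefined for a zero canopy flux.")
  }
  direction <- function(floor, canopy) {
    if_else(sign(floor) == sign(canopy), "same", "opposite")
  }
  out <- tibble(
    floor_share_a_pct = abs(floor_a) / abs(canopy_a) * 100,
    direction_a = direction(floor_a, canopy_a),
    floor_share_b_pct = abs(floor_b) / abs(canopy_b) * 100,
    direction_b = direction(floor_b, canopy_b),
    canopy_diff_pct = abs(abs(canopy_a) - abs(canopy_b)) /
      min(abs(canopy_a), abs(canopy_b)) * 100
  )
  if (!is.null(nep_a) && !is.null(nep_b)) {
    out$nep_contrast <- max(nep_a, nep_b) / min(nep_a, nep_b)
  }
  out
}
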