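#' Describe one flux-gradient measurement system
#'
#' A site configuration holds the geometry and constants of a single
#' two-height gradient system: the upper and lower inlet heights, the
#' canopy height, the zero-plane displacement height `d`, and the von
#' Karman constant. Both a tall above-canopy ("ecosystem") tower and a
#' short understory ("floor") mast are described by the same structure.
#'
#' When `displacement_height` is not supplied it defaults to 2/3 of the
#' canopy height, the standard rule of thumb for dense vegetation. For a
#' forest-floor system the relevant "canopy" is the ground surface, so
#' `canopy_height = 0` gives `d = 0`.
#'
#' @param z_upper Upper inlet height above ground (m).
#' @param z_lower Lower inlet height above ground (m).
#' @param canopy_height Canopy height (m); used only for the default `d`.
#' @param displacement_height Zero-plane displacement `d` (m). Default
#'   `2/3 * canopy_height`.
#' @param von_karman von Karman constant (dimensionless), fixed at 0.4 in
#'   standard micrometeorological practice.
#' @param zeta_height Height (m) at which the supplied stability parameter
#'   z/L was evaluated; defaults to `z_upper`. Used to rescale z/L to the
#'   two inlet heights.
#' @param system_label Free-text label, conventionally `"ecosystem"` or
#'   `"floor"`.
#'
#' @return An object of class `gem_site` (a named list).
#' @examples
#' howland_eco <- site_config(28.2, 23.2, canopy_height = 20,
#'                            system_label = "ecosystem")
#' howland_floor <- site_config(2.6, 1.3, canopy_height = 0,
#'                              system_label = "floor")
#' @export
site_config <- function(z_upper, z_lower, canopy_height,
                        displacement_height = NULL,
                        von_karman = 0.4,
                        zeta_height = z_upper,
                        system_label = "ecosystem") {
  if (is.null(displacement_height)) {
    displacement_height <- 2 / 3 * canopy_height
  }
  stopifnot(is.numeric(z_upper), is.numeric(z_lower),
            is.numeric(displacement_height), is.numeric(von_karman))
  if (!(z_upper > z_lower)) {
    abort("`z_upper` must exceed `z_lower`.")
  }
  if (!(z_lower > displacement_height) || displacement_height < 0) {
    abort("Heights must satisfy z_upper > z_lower > d >= 0.")
  }
  if (zeta_height <= displacement_height) {
    abort("`zeta_height` must lie above the displacement height.")
  }
  site <- structure(
    list(z_upper = z_upper, z_lower = z_lower,
         canopy_height = canopy_height,
         displacement_height = displacement_height,
         von_karman = von_karman,
         zeta_height = zeta_height,
         system_label = system_label),
    class = "gem_site"
  )
  # log height ratio must be positive and finite
  stopifnot(is.finite(log_height_ratio(site)), log_height_ratio(site) > 0)
  site
}

log_height_ratio <- function(site) {
  log((site$z_upper - site$displacement_height) /
        (site$z_lower - site$displacement_height))
}

#' @export
print.gem_site <- function(x, ...) {
  cat("<gem_site> ", x$system_label, "\n",
      "  inlets: ", x$z_lower, " / ", x$z_upper, " m,  d = ",
      signif(x$displacement_height, 4), " m,  k = ", x$von_karman, "\n",
      sep = "")
  invisible(x)
}
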