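#' Integrated similarity function for heat
#'
#' Monin-Obukhov integrated stability correction for heat/scalars,
#' Businger-Dyer form:
#' unstable (`zeta < 0`): `psi_h = 2 * log((1 + x^2) / 2)` with
#' `x = (1 - 16 * zeta)^(1/4)`; stable (`zeta >= 0`): `psi_h = -5 * zeta`.
#' Continuous at neutral with `psi_h(0) = 0`.
#'
#' @param zeta Stability parameter z/L (dimensionless); must be finite.
#' @return Numeric vector of corrections (dimensionless).
#' @examples
#' psi_h(c(-1, 0, 0.1))
#' @export
psi_h <- function(zeta) {
  if (!is.numeric(zeta) || any(!is.finite(zeta))) {
    abort("`zeta` must be finite numeric; handle missing stability upstream.")
  }
  psi_h_(zeta)
}

# NA-tolerant core used inside the pipeline (missing zeta -> NA correction)
psi_h_ <- function(zeta) {
  out <- rep(NA_real_, length(zeta))
  stable <- !is.na(zeta) & zeta >= 0
  unstable <- !is.na(zeta) & zeta < 0
  out[stable] <- -5 * zeta[stable]
  x <- (1 - 16 * zeta[unstable])^0.25
  out[unstable] <- 2 * log((1 + x^2) / 2)
  out
}
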