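#' Lateral cell-wall Young's modulus from the thin-shell force balance
#'
#' For a rod-shaped walled cell with a homogeneous isotropic wall, the turgor
#' load sets the elastic strain of the lateral wall through
#' dP * R / (Y h) = eps, so Y = dP * R / (h * eps). Inputs in MPa, um and nm
#' give Y in MPa.
#'
#' @param turgor turgor pressure dP, MPa.
#' @param radius cell radius R, um.
#' @param thickness wall thickness h, nm.
#' @param strain elastic strain eps, dimensionless (about 0.30 for fission
#'   yeasts).
#' @return Young's modulus in MPa.
#' @export
#' @examples
#' young_modulus(1.0, 1.5, 100, 0.30)   # R/h = 15 -> 50 MPa
young_modulus <- function(turgor, radius, thickness, strain) {
  .check_positive(turgor = turgor, radius = radius,
                  thickness = thickness, strain = strain)
  turgor * (radius * 1e3 / thickness) / strain
}

#' Scale a reference Young's modulus across species
#'
#' The force balance is homogeneous in its inputs, so a known modulus maps to
#' another species by ratios alone: Y = Y_ref * turgor_ratio * radius_ratio /
#' (thickness_ratio * strain_ratio). With half the turgor, twice the radius,
#' twice the wall thickness and equal strain, a 50 MPa wall maps to 25 MPa.
#'
#' @param y_ref reference modulus, MPa.
#' @param turgor_ratio,radius_ratio,thickness_ratio,strain_ratio positive
#'   ratios (target over reference).
#' @return scaled Young's modulus in MPa.
#' @export
scale_young <- function(y_ref, turgor_ratio, radius_ratio,
                        thickness_ratio, strain_ratio = 1) {
  .check_positive(y_ref = y_ref, turgor_ratio = turgor_ratio,
                  radius_ratio = radius_ratio, thickness_ratio = thickness_ratio,
                  strain_ratio = strain_ratio)
  y_ref * turgor_ratio * radius_ratio / (thickness_ratio * strain_ratio)
}

#' Lateral wall tension of a rod-shaped cell
#'
#' T = dP * R; MPa times um is exactly N/m. Half the turgor at twice the
#' radius leaves the tension unchanged.
#'
#' @param turgor turgor pressure dP, MPa.
#' @param radius cell radius R, um.
#' @return wall tension in N/m.
#' @export
wall_tension <- function(turgor, radius) {
  .check_positive(turgor = turgor, radius = radius)
  turgor * radius
}

.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop(nm, " must be positive and finite")
  }
  invisible(TRUE)
}
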