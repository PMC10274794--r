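#' Physical constants used throughout the package
#'
#' Gas constant and the default study temperature. All concentrations in the
#' package are mol/L, pressures MPa, temperatures kelvin.
#'
#' @param temperature_K study temperature in kelvin; defaults to 303.15 K
#'   (30 degrees C, the growth temperature of the yeasts measured).
#' @return a list with elements \code{gas_constant_R} (J/(mol K)) and
#'   \code{default_temperature_T} (K).
#' @export
osmo_constants <- function(temperature_K = 303.15) {
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    stop("temperature must be a positive number of kelvin")
  list(gas_constant_R = 8.314, default_temperature_T = temperature_K)
}

.GAS_CONSTANT <- 8.314     # J / (mol K)
.DEFAULT_TEMP <- 303.15    # K (30 C)

#' Van't Hoff osmotic pressure of a solute concentration
#'
#' Converts a solute concentration to its osmotic pressure, P = C R T. Input
#' mol/L is converted internally to mol/m^3 so that the result is in MPa:
#' 0.40 mol/L at 303.15 K gives 1.008 MPa.
#'
#' @param c_sorbitol concentration in mol/L (vectorised), >= 0.
#' @param temperature temperature in kelvin, > 0.
#' @return pressure in MPa.
#' @seealso [pressure_to_concentration()] for the inverse.
#' @export
#' @examples
#' vant_hoff_pressure(0.40)            # ~ 1.0 MPa
#' vant_hoff_pressure(0.20, 303.15)    # ~ 0.5 MPa
vant_hoff_pressure <- function(c_sorbitol, temperature = .DEFAULT_TEMP) {
  stopifnot(is.numeric(c_sorbitol), is.numeric(temperature))
  if (any(c_sorbitol < 0)) stop("concentration must be non-negative")
  if (any(temperature <= 0)) stop("temperature must be positive (kelvin)")
  # mol/L -> mol/m^3 (x1000); C R T is then Pa; Pa -> MPa (/1e6)
  c_sorbitol * 1000 * .GAS_CONSTANT * temperature / 1e6
}

#' Invert the Van't Hoff relation
#'
#' @param pressure_MPa osmotic pressure in MPa, >= 0.
#' @param temperature temperature in kelvin, > 0.
#' @return concentration in mol/L.
#' @export
pressure_to_concentration <- function(pressure_MPa, temperature = .DEFAULT_TEMP) {
  stopifnot(is.numeric(pressure_MPa), is.numeric(temperature))
  if (any(pressure_MPa < 0)) stop("pressure must be non-negative")
  if (any(temperature <= 0)) stop("temperature must be positive (kelvin)")
  pressure_MPa * 1e6 / (1000 * .GAS_CONSTANT * temperature)
}

#' Combine variance contributions by the delta method
#'
#' Error combination used by all three inversion routines: the variance of the
#' fitted calibration curve (already propagated to concentration units) and the
#' variance of the intact-cell summary statistic (likewise mapped to
#' concentration units) add; the combined standard error is the square root of
#' their sum.
#'
#' @param fit_variance_on_c variance contribution from the fit, (mol/L)^2.
#' @param target_variance_on_c variance contribution from the intact-cell
#'   target statistic, (mol/L)^2.
#' @return combined standard error in mol/L.
#' @export
combine_errors_delta <- function(fit_variance_on_c, target_variance_on_c) {
  stopifnot(is.numeric(fit_variance_on_c), is.numeric(target_variance_on_c))
  if (any(fit_variance_on_c < 0) || any(target_variance_on_c < 0))
    stop("variances must be non-negative")
  sqrt(fit_variance_on_c + target_variance_on_c)
}

#' Isotonic concentration estimate
#'
#' The common currency of the three pipelines: the external sorbitol
#' concentration at which protoplasts match intact cells, with its standard
#' error.
#'
#' @param method one of "volume", "intensity", "rheology".
#' @param c_iso isotonic sorbitol concentration, mol/L.
#' @param c_iso_err combined standard error, mol/L.
#' @param n number of protoplasts (volume/intensity) or tracks (rheology)
#'   behind the estimate.
#' @param note optional diagnostic (e.g. extrapolation warnings).
#' @return an object of class \code{"isotonic_estimate"}.
#' @export
isotonic_estimate <- function(method, c_iso, c_iso_err, n = NA_integer_,
                              note = NULL) {
  method <- match.arg(method, c("volume", "intensity", "rheology"))
  stopifnot(is.numeric(c_iso), length(c_iso) == 1L,
            is.numeric(c_iso_err), length(c_iso_err) == 1L)
  if (c_iso < 0) stop("isotonic concentration must be non-negative")
  if (c_iso_err < 0) stop("error must be non-negative")
  structure(list(method = method, c_iso = c_iso, c_iso_err = c_iso_err,
                 n = n, note = note),
            class = "isotonic_estimate")
}

#' @export
print.isotonic_estimate <- function(x, ...) {
  cat(sprintf("Isotonic sorbitol concentration (%s method): %.2f +/- %.2f mol/L",
              x$method, x$c_iso, x$c_iso_err))
  if (!is.na(x$n)) cat(sprintf("  [n = %d]", x$n))
  cat("\n")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Turgor pressure result
#'
#' @param pressure_MPa turgor pressure in MPa.
#' @param pressure_err_MPa standard error in MPa.
#' @param provenance method label or "average".
#' @return an object of class \code{"turgor_result"}.
#' @export
turgor_result <- function(pressure_MPa, pressure_err_MPa,
                          provenance = "unspecified") {
  stopifnot(is.numeric(pressure_MPa), is.numeric(pressure_err_MPa))
  if (pressure_MPa < 0) stop("turgor pressure must be non-negative")
  if (pressure_err_MPa < 0) stop("pressure error must be non-negative")
  structure(list(pressure_MPa = pressure_MPa,
                 pressure_err_MPa = pressure_err_MPa,
                 provenance = provenance),
            class = "turgor_result")
}

#' @export
print.turgor_result <- function(x, ...) {
  cat(sprintf("Turgor pressure (%s): %s +/- %s MPa\n", x$provenance,
              signif(x$pressure_MPa, 2), signif(x$pressure_err_MPa, 1)))
  invisible(x)
}

#' Convert an isotonic estimate to turgor pressure
#'
#' Applies P = C R T to the isotonic sorbitol concentration; since the growth
#' medium baseline is common to intact cells and protoplasts it cancels in
#' P = Pi_C - Pi_buffer, so only the added sorbitol enters. The error is
#' scaled by the same factor (the conversion is linear).
#'
#' @param estimate an [isotonic_estimate()].
#' @param temperature temperature in kelvin.
#' @return a [turgor_result()].
#' @export
turgor_from_isotonic <- function(estimate, temperature = .DEFAULT_TEMP) {
  stopifnot(inherits(estimate, "isotonic_estimate"))
  turgor_result(vant_hoff_pressure(estimate$c_iso, temperature),
                vant_hoff_pressure(estimate$c_iso_err, temperature),
                provenance = estimate$method)
}

#' Cross-method average of turgor estimates
#'
#' The reported study-level value: the arithmetic mean of the per-method
#' pressures, with the sample standard deviation (n - 1 denominator) across
#' methods as the error.
#'
#' @param estimates a list of [turgor_result()] objects, or a numeric vector
#'   of pressures in MPa; at least two values.
#' @return a [turgor_result()] with provenance \code{"average"}.
#' @export
combine_methods <- function(estimates) {
  if (is.numeric(estimates)) {
    p <- estimates
  } else {
    stopifnot(is.list(estimates),
              all(vapply(estimates, inherits, logical(1), "turgor_result")))
    p <- vapply(estimates, function(e) e$pressure_MPa, numeric(1))
  }
  if (length(p) < 2L)
    stop("at least two method estimates are needed (SD undefined otherwise)")
  turgor_result(mean(p), stats::sd(p), provenance = "average")
}
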