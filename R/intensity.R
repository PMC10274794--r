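#' Background-correct and calibrate cytoplasmic intensities
#'
#' Each cell's ROI mean is corrected by its background and divided by the
#' mean corrected intensity of the intact-cell calibration population imaged
#' on the same slide, so that 1.0 means "same cytoplasmic concentration as
#' intact cells". Slide-level calibration removes day-to-day and slide-to-slide
#' multiplicative gain.
#'
#' @param records data.frame with columns \code{slide_id}, \code{roi_mean},
#'   \code{background_mean} (one row per cell; other columns are carried
#'   through).
#' @param calibration data.frame with columns \code{slide_id},
#'   \code{intact_mean} (> 0); one row per slide.
#' @return \code{records} with a \code{normalized} column; cells whose
#'   corrected intensity is not positive are dropped with a message giving
#'   the count.
#' @export
normalize_intensity <- function(records, calibration) {
  req <- c("slide_id", "roi_mean", "background_mean")
  if (!all(req %in% names(records)))
    stop("intensity records need columns: ", paste(req, collapse = ", "))
  if (!all(c("slide_id", "intact_mean") %in% names(calibration)))
    stop("calibration needs columns slide_id, intact_mean")
  if (any(calibration$intact_mean <= 0))
    stop("calibration intact_mean must be positive")
  m <- match(records$slide_id, calibration$slide_id)
  if (anyNA(m)) {
    bad <- unique(records$slide_id[is.na(m)])
    stop("no calibration for slide(s): ", paste(bad, collapse = ", "))
  }
  corrected <- records$roi_mean - records$background_mean
  keep <- corrected > 0
  if (any(!keep))
    message(sum(!keep), " record(s) with non-positive corrected intensity excluded")
  records <- records[keep, , drop = FALSE]
  records$normalized <- corrected[keep] / calibration$intact_mean[m[keep]]
  records
}

#' Linear model of normalized intensity versus sorbitol concentration
#'
#' As protoplasts shrink under sorbitol, the cytoplasmic fluorophore
#' concentrates; near the isotonic point the per-condition mean normalized
#' intensity is well described by a straight line in sorbitol concentration.
#' The fit is OLS through the per-condition means, optionally restricted to a
#' concentration window around the intact-cell intensity.
#'
#' @param data data.frame with columns \code{sorbitol_mol_per_L} and
#'   \code{normalized} (per cell; condition means are taken internally), or
#'   already one row per condition.
#' @param window optional numeric length-2 interval of sorbitol concentrations
#'   (mol/L) to fit within; default uses all conditions.
#' @return an object of class \code{"intensity_fit"} with \code{slope}
#'   (1/(mol/L)), \code{intercept}, their covariance and the fitted window.
#' @export
fit_intensity <- function(data, window = NULL) {
  if (!all(c("sorbitol_mol_per_L", "normalized") %in% names(data)))
    stop("need columns sorbitol_mol_per_L and normalized")
  means <- stats::aggregate(list(normalized = data$normalized),
                            list(conc = data$sorbitol_mol_per_L), mean)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    window <- sort(window)
    means <- means[means$conc >= window[1] & means$conc <= window[2], ,
                   drop = FALSE]
  } else {
    window <- range(means$conc)
  }
  if (length(unique(means$conc)) < 2L)
    stop("need at least 2 distinct concentrations inside the window")
  fit <- stats::lm(normalized ~ conc, data = means)
  b <- stats::coef(fit)
  # vcov warns on zero-residual (interpolating) fits; that case is legitimate
  V <- suppressWarnings(stats::vcov(fit))
  # two-point windows interpolate exactly; report zero parameter variance
  if (fit$df.residual == 0L || !all(is.finite(V))) V[] <- 0
  if (unname(b[2]) <= 0)
    warning("fitted slope is not positive; intensity should rise with sorbitol")
  structure(list(slope = unname(b[2]), intercept = unname(b[1]),
                 vcov = matrix(c(V[1, 1], V[1, 2], V[2, 1], V[2, 2]), 2, 2,
                               dimnames = list(c("intercept", "slope"),
                                               c("intercept", "slope"))),
                 window = window, points = means, n_cells = nrow(data),
                 lm = fit),
            class = "intensity_fit")
}

#' @export
coef.intensity_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
vcov.intensity_fit <- function(object, ...) object$vcov

#' Predicted normalized intensity at a sorbitol concentration
#' @param object a [fit_intensity()] result.
#' @param conc sorbitol concentration, mol/L (vectorised).
#' @param ... unused.
#' @export
predict.intensity_fit <- function(object, conc, ...)
  object$intercept + object$slope * conc

#' @export
residuals.intensity_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
print.intensity_fit <- function(x, ...) {
  cat("Normalized-intensity calibration line: I = intercept + slope * C\n")
  cat(sprintf("  intercept = %.4g   slope = %.4g per (mol/L)\n",
              x$intercept, x$slope))
  cat(sprintf("  fitted over C in [%.2f, %.2f] mol/L (%d conditions, %d cells)\n",
              x$window[1], x$window[2], nrow(x$points), x$n_cells))
  invisible(x)
}

#' @export
summary.intensity_fit <- function(object, ...) {
  print(object)
  cat("\nParameter standard errors:\n")
  print(sqrt(diag(object$vcov)))
  invisible(summary(object$lm))
}

#' @export
plot.intensity_fit <- function(x, target = 1, ...) {
  graphics::plot(x$points$conc, x$points$normalized,
                 xlab = "sorbitol (mol/L)", ylab = "normalized intensity",
                 main = "Cytoplasmic intensity vs sorbitol", ...)
  graphics::abline(a = x$intercept, b = x$slope, col = "firebrick")
  graphics::abline(h = target, lty = 2)
  invisible(x)
}

#' Invert an intensity fit at the intact-cell intensity
#'
#' Solves intercept + slope * C = target for the sorbitol concentration at
#' which protoplast intensity matches intact cells (target 1.0 after
#' calibration). The error combines, by the delta method, the fit parameter
#' covariance and the between-replicate variance of the intact-cell mean
#' intensity.
#'
#' @param fit a [fit_intensity()] result.
#' @param target intact-cell normalized intensity (default 1.0).
#' @param target_var between-replicate variance of the intact normalized mean
#'   (dimensionless^2).
#' @param n number of protoplasts behind the fit (for reporting).
#' @return an [isotonic_estimate()] with method "intensity"; a note is set
#'   when the solution falls outside the fitted window.
#' @export
invert_intensity <- function(fit, target = 1.0, target_var = 0,
                             n = NA_integer_) {
  stopifnot(inherits(fit, "intensity_fit"))
  if (fit$slope == 0) stop("zero slope: intensity does not constrain concentration")
  c_iso <- (target - fit$intercept) / fit$slope
  if (c_iso < 0)
    stop(sprintf("isotonic concentration is negative (%.3f mol/L)", c_iso))
  # gradient of (t - a)/b in (a, b), plus dc/dt = 1/b for the target variance
  g <- c(-1 / fit$slope, -(target - fit$intercept) / fit$slope^2)
  var_fit <- drop(t(g) %*% fit$vcov %*% g)
  var_target <- target_var / fit$slope^2
  note <- NULL
  if (c_iso < fit$window[1] || c_iso > fit$window[2])
    note <- sprintf("solution %.3f mol/L lies outside the fitted window [%.2f, %.2f]",
                    c_iso, fit$window[1], fit$window[2])
  isotonic_estimate("intensity", c_iso,
                    combine_errors_delta(var_fit, var_target),
                    n = if (is.na(n)) fit$n_cells else n, note = note)
}
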