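#' Time-averaged mean squared displacement of a 2D track
#'
#' For lag k the MSD uses all overlapping pairs of positions k frames apart:
#' MSD(k dt) = mean_i [(x_{i+k} - x_i)^2 + (y_{i+k} - y_i)^2]. Tracks must be
#' uniformly sampled (nominally 10 ms at 100 fps).
#'
#' @param track data.frame with columns \code{t_s}, \code{x_um}, \code{y_um}
#'   (one row per frame, time-ordered), or a list with elements \code{times},
#'   \code{x}, \code{y}.
#' @param max_lag number of lags to compute (default 10, the fitting window).
#' @param tol relative tolerance on frame-interval uniformity.
#' @return an object of class \code{"msd_curve"}: \code{lags} (s), \code{msd}
#'   (um^2), \code{n_pairs} and \code{sem} per lag.
#' @export
compute_msd <- function(track, max_lag = 10, tol = 1e-6) {
  if (is.data.frame(track)) {
    times <- track$t_s; x <- track$x_um; y <- track$y_um
  } else {
    times <- track$times; x <- track$x; y <- track$y
  }
  n <- length(x)
  if (n < max_lag + 1L)
    stop(sprintf("track too short: %d frames, need >= %d", n, max_lag + 1L))
  dt <- diff(times)
  if (any(dt <= 0)) stop("track times must be strictly increasing")
  if (max(abs(dt - dt[1])) > tol * dt[1])
    stop("track is not uniformly sampled")
  dt <- dt[1]
  msd <- n_pairs <- sem <- numeric(max_lag)
  for (k in seq_len(max_lag)) {
    sq <- (x[(k + 1):n] - x[1:(n - k)])^2 + (y[(k + 1):n] - y[1:(n - k)])^2
    msd[k] <- mean(sq)
    n_pairs[k] <- n - k
    sem[k] <- stats::sd(sq) / sqrt(n - k)
  }
  structure(list(lags = dt * seq_len(max_lag), msd = msd,
                 n_pairs = n_pairs, sem = sem),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags, dt = %g s, MSD(dt) = %.4g um^2\n",
              length(x$lags), x$lags[1], x$msd[1]))
  invisible(x)
}

# MSD for an ensemble of equal-length tracks held as frames x tracks
# matrices; returns a max_lag x n_tracks matrix.
.msd_matrix <- function(x, y, max_lag) {
  n <- nrow(x)
  if (n < max_lag + 1L) stop("tracks too short for requested lags")
  out <- matrix(NA_real_, max_lag, ncol(x))
  for (k in seq_len(max_lag)) {
    dx <- x[(k + 1):n, , drop = FALSE] - x[1:(n - k), , drop = FALSE]
    dy <- y[(k + 1):n, , drop = FALSE] - y[1:(n - k), , drop = FALSE]
    out[k, ] <- colMeans(dx * dx + dy * dy)
  }
  out
}

# Slope through the origin of MSD vs lag time, divided by 4.
.deff_slope <- function(lags, msd) sum(lags * msd) / (4 * sum(lags * lags))

#' Effective diffusion coefficient from truncated MSD curves
#'
#' Fits the first \code{n_points} lags of the ensemble-mean MSD to the 2D
#' Brownian law MSD(tau) = 4 D_eff tau by least squares through the origin.
#' The SEM is taken across per-track D_eff values fitted the same way.
#'
#' @param curves a list of [compute_msd()] results (all with at least
#'   \code{n_points} lags and a common lag grid), or a numeric matrix of MSD
#'   values (lags x tracks) with \code{lags} supplied.
#' @param n_points number of lags in the fit window (default 10).
#' @param lags lag times in seconds, required when \code{curves} is a matrix.
#' @return an object of class \code{"deff_estimate"}: \code{d_eff} (um^2/s),
#'   \code{sem}, \code{n_tracks}.
#' @export
fit_deff <- function(curves, n_points = 10, lags = NULL) {
  if (is.matrix(curves)) {
    if (is.null(lags)) stop("matrix input needs the lag times")
    msd_mat <- curves
  } else {
    if (!length(curves)) stop("no MSD curves supplied")
    stopifnot(all(vapply(curves, inherits, logical(1), "msd_curve")))
    short <- vapply(curves, function(cv) length(cv$lags) < n_points, logical(1))
    if (all(short)) stop("no curve has the requested number of lags")
    if (any(short))
      message(sum(short), " curve(s) with fewer than ", n_points,
              " lags excluded")
    curves <- curves[!short]
    lags <- curves[[1]]$lags
    msd_mat <- vapply(curves, function(cv) cv$msd[seq_len(n_points)],
                      numeric(n_points))
    msd_mat <- matrix(msd_mat, nrow = n_points)
  }
  lags <- lags[seq_len(n_points)]
  msd_mat <- msd_mat[seq_len(n_points), , drop = FALSE]
  d_each <- apply(msd_mat, 2, .deff_slope, lags = lags)
  d_eff <- .deff_slope(lags, rowMeans(msd_mat))
  n <- ncol(msd_mat)
  sem <- if (n > 1L) stats::sd(d_each) / sqrt(n) else NA_real_
  structure(list(d_eff = d_eff, sem = sem, n_tracks = n,
                 d_per_track = d_each),
            class = "deff_estimate")
}

#' @export
print.deff_estimate <- function(x, ...) {
  cat(sprintf("D_eff = %.4g +/- %.2g um^2/s  (%d tracks)\n",
              x$d_eff, x$sem, x$n_tracks))
  invisible(x)
}

#' Fit the Phillies concentration model for cytGEMs diffusion
#'
#' Tracer diffusion in a crowded cytoplasm follows the Phillies law
#' D_eff = D0 exp(-beta (C + C0)), with D0 the Stokes-Einstein diffusion of a
#' 40-nm sphere in water (13.56 um^2/s, a fixed constant), C the added
#' sorbitol and C0 the growth-medium osmolarity (fixed, not fitted). beta is
#' estimated by regressing log(D_eff/D0) on -(C + C0) through the origin;
#' a nonlinear least-squares fit in linear space is available and agrees on
#' clean data.
#'
#' @param data data.frame with columns \code{sorbitol_mol_per_L} and
#'   \code{d_eff} (per-condition mean effective diffusion, um^2/s).
#' @param c0_medium growth-medium osmolarity, mol/L.
#' @param d0 dilute-limit diffusion, um^2/s (default 13.56).
#' @param fit_space "log" (default, linearised) or "linear"
#'   (\code{stats::nls} on the exponential).
#' @return an object of class \code{"phillies_fit"}: \code{beta} (L/mol),
#'   \code{beta_variance}, \code{d0}, \code{c0_medium}.
#' @export
fit_phillies <- function(data, c0_medium, d0 = 13.56,
                         fit_space = c("log", "linear")) {
  fit_space <- match.arg(fit_space)
  if (!all(c("sorbitol_mol_per_L", "d_eff") %in% names(data)))
    stop("need columns sorbitol_mol_per_L and d_eff")
  conc <- data$sorbitol_mol_per_L; d <- data$d_eff
  if (length(unique(conc)) < 2L)
    stop("need at least 2 distinct sorbitol concentrations")
  if (any(d <= 0)) stop("effective diffusion must be positive")
  if (any(d >= d0))
    stop("d_eff >= d0 is unphysical for the Phillies model")
  x <- conc + c0_medium
  y <- log(d / d0)
  beta <- -sum(x * y) / sum(x * x)
  resid <- y + beta * x
  beta_var <- if (length(x) > 1L) sum(resid^2) / (length(x) - 1L) / sum(x * x)
              else 0
  if (fit_space == "linear") {
    # scaleOffset makes the convergence test valid for zero-residual data
    nl <- stats::nls(d ~ d0 * exp(-b * x), start = list(b = beta),
                     data = data.frame(d = d, x = x),
                     control = stats::nls.control(maxiter = 100,
                                                  scaleOffset = 1))
    beta <- unname(stats::coef(nl)["b"])
    beta_var <- unname(stats::vcov(nl)[1, 1])
  }
  if (beta <= 0) warning("fitted beta is not positive; diffusion should fall with concentration")
  structure(list(beta = beta, beta_variance = beta_var, d0 = d0,
                 c0_medium = c0_medium, fit_space = fit_space,
                 points = data.frame(conc = conc, d_eff = d)),
            class = "phillies_fit")
}

#' @export
coef.phillies_fit <- function(object, ...)
  c(beta = object$beta, d0 = object$d0, c0_medium = object$c0_medium)

#' Predicted effective diffusion at a sorbitol concentration
#' @param object a [fit_phillies()] result.
#' @param conc added sorbitol concentration, mol/L (vectorised).
#' @param ... unused.
#' @export
predict.phillies_fit <- function(object, conc, ...)
  object$d0 * exp(-object$beta * (conc + object$c0_medium))

#' @export
print.phillies_fit <- function(x, ...) {
  cat("Phillies model: D_eff = D0 exp(-beta (C + C0))\n")
  cat(sprintf("  beta = %.4g L/mol (SE %.2g), D0 = %g um^2/s, C0 = %g mol/L [%s fit]\n",
              x$beta, sqrt(x$beta_variance), x$d0, x$c0_medium, x$fit_space))
  invisible(x)
}

#' @export
plot.phillies_fit <- function(x, d_eff_intact = NULL, ...) {
  graphics::plot(x$points$conc, x$points$d_eff,
                 xlab = "sorbitol (mol/L)", ylab = expression(D[eff]~(mu*m^2/s)),
                 main = "cytGEMs diffusion vs sorbitol", ...)
  cc <- seq(min(x$points$conc), max(x$points$conc), length.out = 100)
  graphics::lines(cc, predict(x, cc), col = "firebrick")
  if (!is.null(d_eff_intact)) graphics::abline(h = d_eff_intact, lty = 2)
  invisible(x)
}

#' Invert a Phillies fit at the intact-cell diffusion
#'
#' Solves D0 exp(-beta (C + C0)) = D_eff,intact for the sorbitol
#' concentration at which protoplast cytGEMs mobility matches intact cells:
#' C_iso = log(D0/D_eff)/beta - C0. The error combines, by the delta method,
#' the beta variance and the SEM of the intact-cell D_eff.
#'
#' @param fit a [fit_phillies()] result.
#' @param d_eff_intact a [fit_deff()] result for intact cells, or a bare
#'   number in um^2/s (then \code{sem} supplies its uncertainty).
#' @param sem SEM of the intact D_eff when given as a bare number.
#' @return an [isotonic_estimate()] with method "rheology".
#' @export
invert_phillies <- function(fit, d_eff_intact, sem = 0) {
  stopifnot(inherits(fit, "phillies_fit"))
  if (inherits(d_eff_intact, "deff_estimate")) {
    n <- d_eff_intact$n_tracks
    sem <- d_eff_intact$sem
    d <- d_eff_intact$d_eff
  } else {
    n <- NA_integer_
    d <- d_eff_intact
  }
  if (!is.finite(d) || d <= 0 || d >= fit$d0)
    stop("intact-cell D_eff must lie strictly between 0 and d0")
  c_iso <- log(fit$d0 / d) / fit$beta - fit$c0_medium
  if (c_iso < 0)
    stop(sprintf("isotonic concentration is negative (%.3f mol/L)", c_iso))
  var_fit <- (log(fit$d0 / d) / fit$beta^2)^2 * fit$beta_variance
  var_target <- (1 / (fit$beta * d))^2 * (if (is.na(sem)) 0 else sem)^2
  isotonic_estimate("rheology", c_iso,
                    combine_errors_delta(var_fit, var_target), n = n)
}
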