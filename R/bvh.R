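#' Summarise a population of cell volumes
#'
#' Central statistic of a volume distribution, and the spread of that
#' statistic across experimental replicates. The median is the default
#' (robust against the long right tail of asynchronous populations); the mean
#' is available as an option.
#'
#' @param volumes per-cell volumes in um^3, all > 0.
#' @param statistic "median" (default) or "mean".
#' @param replicate optional replicate labels, same length as \code{volumes};
#'   when given, \code{spread} is the SD of the per-replicate statistics.
#' @return list with \code{summary} (um^3) and \code{spread} (um^3, \code{NA}
#'   without replicate labels).
#' @export
summarize_population <- function(volumes, statistic = c("median", "mean"),
                                 replicate = NULL) {
  statistic <- match.arg(statistic)
  if (length(volumes) == 0L) stop("empty volume population")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("volumes must be positive and finite")
  stat_fun <- if (statistic == "median") stats::median else mean
  spread <- NA_real_
  if (!is.null(replicate)) {
    stopifnot(length(replicate) == length(volumes))
    per_rep <- tapply(volumes, replicate, stat_fun)
    summary <- mean(per_rep)
    if (length(per_rep) > 1L) spread <- stats::sd(per_rep)
  } else {
    summary <- stat_fun(volumes)
  }
  list(summary = summary, spread = spread)
}

# Collapse a per-cell volume table to one summary point per
# condition x replicate (pooled = FALSE) or per condition (pooled = TRUE).
.bvh_points <- function(data, statistic, pooled) {
  c_total <- data$sorbitol_mol_per_L + data$medium_baseline_mol_per_L
  if (any(c_total <= 0))
    stop("zero or negative total osmolarity cannot be used as a fit abscissa")
  key <- if (pooled) list(c_total = c_total)
         else list(c_total = c_total, replicate = data$replicate)
  stat_fun <- if (statistic == "median") stats::median else mean
  agg <- stats::aggregate(list(volume = data$volume_um3), key, stat_fun)
  agg[order(agg$c_total), , drop = FALSE]
}

#' Fit the Boyle Van't Hoff ideal-osmometer law to protoplast volumes
#'
#' Protoplasts carry no turgor and behave as ideal osmometers: their
#' equilibrium volume is linear in the inverse of the total external
#' osmolarity, V = m0 / C_total + b0, with slope m0 (apparent osmotically
#' active content, um^3 mol/L) and intercept b0 (non-osmotic volume, um^3).
#' The fit is ordinary least squares on population summary volumes, one point
#' per condition (and per replicate unless \code{pooled}); the abscissa is the
#' total osmolarity, added sorbitol plus growth-medium baseline.
#'
#' @param data per-cell volume table: columns \code{sorbitol_mol_per_L},
#'   \code{medium_baseline_mol_per_L}, \code{replicate}, \code{volume_um3},
#'   and optionally \code{is_protoplast} (non-protoplast rows are dropped).
#' @param statistic central statistic per population, "median" or "mean".
#' @param pooled pool replicates into one point per condition? Default keeps
#'   replicates as separate points.
#' @return an object of class \code{"bvh_fit"}: coefficients \code{m0},
#'   \code{b0}, their covariance, \code{r_squared}, the fitted points and the
#'   number of cells used.
#' @export
#' @examples
#' tab <- data.frame(sorbitol_mol_per_L = rep(c(0.2, 0.7, 1.2), each = 2),
#'                   medium_baseline_mol_per_L = 0.3,
#'                   replicate = rep(1:2, 3), is_protoplast = TRUE,
#'                   volume_um3 = 30 / rep(c(0.5, 1.0, 1.5), each = 2) + 20)
#' fit <- fit_bvh(tab)
#' coef(fit)   # m0 = 30, b0 = 20
fit_bvh <- function(data, statistic = c("median", "mean"), pooled = FALSE) {
  statistic <- match.arg(statistic)
  req <- c("sorbitol_mol_per_L", "medium_baseline_mol_per_L",
           "replicate", "volume_um3")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("volume table lacks columns: ", paste(missing_cols, collapse = ", "))
  if ("is_protoplast" %in% names(data)) data <- data[data$is_protoplast, ]
  if (!nrow(data)) stop("no protoplast rows to fit")
  pts <- .bvh_points(data, statistic, pooled)
  if (length(unique(pts$c_total)) < 3L)
    stop("need at least 3 distinct total osmolarities to fit the osmometer law")
  fit <- stats::lm(volume ~ I(1 / c_total), data = pts)
  b <- stats::coef(fit)
  # vcov warns on zero-residual (interpolating) fits; that case is legitimate
  V <- suppressWarnings(stats::vcov(fit))     # order: (b0, m0)
  m0 <- unname(b[2]); b0 <- unname(b[1])
  if (m0 <= 0) warning("fitted m0 is not positive; data are not osmometer-like")
  if (b0 < 0) warning("fitted non-osmotic volume b0 is negative")
  structure(list(
    m0 = m0, b0 = b0,
    vcov = matrix(c(V[2, 2], V[2, 1], V[1, 2], V[1, 1]), 2, 2,
                  dimnames = list(c("m0", "b0"), c("m0", "b0"))),
    r_squared = {
      tss <- sum((pts$volume - mean(pts$volume))^2)
      if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
    },
    n_points = nrow(pts), n_cells = nrow(data),
    statistic = statistic, points = pts, lm = fit),
    class = "bvh_fit")
}

#' @export
coef.bvh_fit <- function(object, ...) c(m0 = object$m0, b0 = object$b0)

#' @export
vcov.bvh_fit <- function(object, ...) object$vcov

#' Predicted protoplast volume at a total osmolarity
#' @param object a [fit_bvh()] result.
#' @param c_total total external osmolarity, mol/L (vectorised), > 0.
#' @param ... unused.
#' @return predicted volume in um^3.
#' @export
predict.bvh_fit <- function(object, c_total, ...) {
  if (any(c_total <= 0)) stop("total osmolarity must be positive")
  object$m0 / c_total + object$b0
}

#' @export
residuals.bvh_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
print.bvh_fit <- function(x, ...) {
  cat("Boyle Van't Hoff osmometer fit: V = m0/C_total + b0\n")
  cat(sprintf("  m0 = %.3g um^3 mol/L   b0 = %.3g um^3   (R^2 = %.4f)\n",
              x$m0, x$b0, x$r_squared))
  cat(sprintf("  %d summary points from %d cells (%s per population)\n",
              x$n_points, x$n_cells, x$statistic))
  invisible(x)
}

#' @export
summary.bvh_fit <- function(object, ...) {
  s <- summary(object$lm)
  cat("Boyle Van't Hoff osmometer fit\n\n")
  print(object)
  cat("\nParameter standard errors:\n")
  print(sqrt(diag(object$vcov)))
  invisible(s)
}

#' @export
plot.bvh_fit <- function(x, target_volume = NULL, ...) {
  inv_c <- 1 / x$points$c_total
  graphics::plot(inv_c, x$points$volume,
                 xlab = "1 / C_total (L/mol)", ylab = expression(V~(mu*m^3)),
                 main = "Boyle Van't Hoff plot", ...)
  graphics::abline(a = x$b0, b = x$m0, col = "firebrick")
  if (!is.null(target_volume))
    graphics::abline(h = target_volume, lty = 2)
  invisible(x)
}

#' Invert a Boyle Van't Hoff fit at the intact-cell volume
#'
#' Solves V = m0/C_total + b0 for the total osmolarity at which the protoplast
#' volume matches the intact-cell summary volume, then subtracts the medium
#' baseline to give the isotonic sorbitol concentration. The standard error
#' combines, by the first-order delta method, the fit parameter covariance and
#' the spread of the intact-cell summary volume.
#'
#' @param fit a [fit_bvh()] result.
#' @param target_volume intact-cell summary volume, um^3; must exceed b0.
#' @param medium_baseline growth-medium osmolarity, mol/L.
#' @param target_spread SD of the intact-cell summary volume across
#'   replicates, um^3 (0 if unknown).
#' @param n number of intact cells behind the target (for reporting).
#' @param bootstrap,data,n_boot when \code{bootstrap = TRUE} the error is
#'   instead estimated by resampling cells within each condition x replicate
#'   of \code{data} (the per-cell table used for the fit), \code{n_boot}
#'   times; the delta-method error remains the default.
#' @return an [isotonic_estimate()] with method "volume".
#' @export
invert_bvh <- function(fit, target_volume, medium_baseline,
                       target_spread = 0, n = NA_integer_,
                       bootstrap = FALSE, data = NULL, n_boot = 1000) {
  stopifnot(inherits(fit, "bvh_fit"))
  if (target_volume <= fit$b0)
    stop("target volume is below the non-osmotic volume b0: no positive solution")
  denom <- target_volume - fit$b0
  c_total <- fit$m0 / denom
  c_iso <- c_total - medium_baseline
  if (c_iso < 0)
    stop(sprintf(paste0("isotonic sorbitol concentration is negative ",
                        "(%.3f mol/L): intact cells appear hypotonic to the ",
                        "growth medium"), c_iso))
  if (isTRUE(bootstrap)) {
    if (is.null(data)) stop("bootstrap error estimation needs the per-cell table")
    err <- .bvh_bootstrap_err(data, fit$statistic, target_volume,
                              medium_baseline, n_boot)
  } else {
    # gradient of c_total = m0/(V - b0) in (m0, b0); dC/dV = -dC/db0
    g <- c(1 / denom, fit$m0 / denom^2)
    var_fit <- drop(t(g) %*% fit$vcov %*% g)
    var_target <- (fit$m0 / denom^2)^2 * target_spread^2
    err <- combine_errors_delta(var_fit, var_target)
  }
  isotonic_estimate("volume", c_iso, err,
                    n = if (is.na(n)) fit$n_cells else n)
}

.bvh_bootstrap_err <- function(data, statistic, target_volume,
                               medium_baseline, n_boot) {
  if ("is_protoplast" %in% names(data)) data <- data[data$is_protoplast, ]
  grp <- interaction(data$sorbitol_mol_per_L, data$replicate, drop = TRUE)
  idx <- split(seq_len(nrow(data)), grp)
  vals <- vapply(seq_len(n_boot), function(b) {
    take <- unlist(lapply(idx, function(i) i[sample.int(length(i),
                                                        replace = TRUE)]),
                   use.names = FALSE)
    f <- fit_bvh(data[take, ], statistic = statistic)
    f$m0 / (target_volume - f$b0) - medium_baseline
  }, numeric(1))
  stats::sd(vals)
}
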