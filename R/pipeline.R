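.baseline_of <- function(df) {
  b <- unique(df$medium_baseline_mol_per_L)
  if (length(b) != 1L)
    stop("tables must use a single medium baseline osmolarity; found: ",
         paste(format(b), collapse = ", "))
  b
}

#' Volume method: isotonic concentration from a per-cell volume table
#'
#' Summarises the intact-cell population (median per replicate, averaged,
#' with the between-replicate SD as its spread), fits the Boyle Van't Hoff
#' law to the protoplast populations and inverts it at the intact summary
#' volume.
#'
#' @param volume_table data.frame in the volume schema (see
#'   [read_volume_table()]).
#' @param statistic central statistic, "median" (default) or "mean".
#' @param pooled pool replicates in the fit?
#' @return list with the [isotonic_estimate()] (\code{estimate}), the
#'   \code{fit}, and the intact \code{target}/\code{spread}.
#' @export
estimate_volume_method <- function(volume_table,
                                   statistic = c("median", "mean"),
                                   pooled = FALSE) {
  statistic <- match.arg(statistic)
  baseline <- .baseline_of(volume_table)
  intact <- volume_table[!volume_table$is_protoplast, ]
  proto <- volume_table[volume_table$is_protoplast, ]
  if (!nrow(intact)) stop("no intact-cell rows: cannot set the inversion target")
  tgt <- summarize_population(intact$volume_um3, statistic,
                              replicate = intact$replicate)
  fit <- fit_bvh(proto, statistic = statistic, pooled = pooled)
  est <- invert_bvh(fit, tgt$summary, baseline,
                    target_spread = if (is.na(tgt$spread)) 0 else tgt$spread,
                    n = nrow(proto))
  list(estimate = est, fit = fit, target = tgt$summary, spread = tgt$spread)
}

#' Choose the concentration window bracketing the intact intensity
#'
#' Implements "close to the intact-cell values": ranks conditions by the
#' distance of their mean normalized intensity from the target and returns
#' the concentration range of the \code{k} nearest.
#'
#' @param normalized data.frame with \code{sorbitol_mol_per_L} and
#'   \code{normalized} per cell.
#' @param target intact-cell normalized intensity (1.0).
#' @param k number of conditions to keep (default 3; all if fewer exist).
#' @return length-2 concentration interval.
#' @export
intensity_window <- function(normalized, target = 1.0, k = 3) {
  means <- stats::aggregate(list(normalized = normalized$normalized),
                            list(conc = normalized$sorbitol_mol_per_L), mean)
  k <- min(k, nrow(means))
  keep <- means[order(abs(means$normalized - target)), ][seq_len(k), ]
  range(keep$conc)
}

#' Intensity method: isotonic concentration from a per-cell intensity table
#'
#' Builds the slide calibration from the intact-cell rows (mean
#' background-corrected intensity per slide), normalizes the protoplast
#' records, fits a line through the per-condition mean normalized intensities
#' within a window of conditions close to the intact value, and inverts it at
#' 1.0.
#'
#' @param intensity_table data.frame in the intensity schema (see
#'   [read_intensity_table()]).
#' @param window "bracket" (default: the \code{k} conditions nearest the
#'   intact intensity), "all", or an explicit numeric interval in mol/L.
#' @param k number of conditions for the bracketing window.
#' @return list with the [isotonic_estimate()] (\code{estimate}), the
#'   \code{fit}, the normalized records and the intact target variance.
#' @export
estimate_intensity_method <- function(intensity_table, window = "bracket",
                                      k = 3) {
  .baseline_of(intensity_table)
  intact <- intensity_table[!intensity_table$is_protoplast, ]
  proto <- intensity_table[intensity_table$is_protoplast, ]
  if (!nrow(intact)) stop("no intact-cell rows: cannot calibrate intensities")
  corr <- intact$roi_mean - intact$background_mean
  cal <- stats::aggregate(list(intact_mean = corr),
                          list(slide_id = intact$slide_id), mean)
  norm <- normalize_intensity(proto, cal)
  norm_int <- normalize_intensity(intact, cal)
  # intact normalized means per replicate; self-calibration makes the
  # between-replicate variance degenerate (exactly 1 per slide), in which
  # case the within-slide SE of the mean is used instead
  rep_means <- tapply(norm_int$normalized, norm_int$replicate, mean)
  target_var <- if (length(rep_means) > 1L) stats::var(rep_means) else 0
  if (target_var < .Machine$double.eps) {
    se2 <- tapply(norm_int$normalized, norm_int$replicate,
                  function(z) stats::var(z) / length(z))
    target_var <- mean(se2)
  }
  win <- if (identical(window, "bracket")) intensity_window(norm, 1.0, k)
         else if (identical(window, "all")) NULL
         else window
  fit <- fit_intensity(norm, window = win)
  est <- invert_intensity(fit, target = 1.0, target_var = target_var,
                          n = nrow(norm))
  list(estimate = est, fit = fit, normalized = norm, target_var = target_var)
}

# per-condition MSD -> D_eff. Tracks are stored contiguously (readers sort
# them); rows of one track are a run, so run-length encoding replaces
# grouping. Equal-length ensembles take a matrix fast path.
.deff_of_group <- function(df, n_points, min_frames) {
  runs <- rle(df$track_id)
  if (is.unsorted(df$frame[seq_len(min(runs$lengths[1], nrow(df)))]))
    df <- df[order(df$track_id, df$frame), , drop = FALSE]
  runs <- rle(df$track_id)
  counts <- runs$lengths
  if (any(counts < min_frames)) {
    message(sum(counts < min_frames), " track(s) shorter than ", min_frames,
            " frames excluded")
    keep <- counts >= min_frames
    df <- df[rep(keep, counts), , drop = FALSE]
    counts <- counts[keep]
  }
  if (!nrow(df)) stop("no usable tracks in a condition")
  dt <- stats::median(diff(df$t_s[seq_len(counts[1])]))
  lags <- dt * seq_len(n_points)
  if (length(unique(counts)) == 1L) {
    nf <- counts[1]
    x <- matrix(df$x_um, nf); y <- matrix(df$y_um, nf)
    msd <- .msd_matrix(x, y, n_points)
    fit_deff(msd, n_points = n_points, lags = lags)
  } else {
    idx <- rep.int(seq_along(counts), counts)
    curves <- lapply(split(seq_len(nrow(df)), idx), function(i)
      compute_msd(df[i, , drop = FALSE], max_lag = n_points))
    fit_deff(curves, n_points = n_points)
  }
}

#' Rheology method: isotonic concentration from a cytGEMs track table
#'
#' Computes per-condition effective diffusion (truncated-MSD fit), fits the
#' Phillies concentration model to the protoplast conditions and inverts it
#' at the intact-cell diffusion.
#'
#' @param track_table data.frame in the track schema (see
#'   [read_track_table()]).
#' @param n_points MSD lags in the diffusion fit (default 10).
#' @param d0 dilute-limit tracer diffusion, um^2/s.
#' @param fit_space Phillies fit space, "log" or "linear".
#' @param min_frames minimum frames for a track to contribute (default 11,
#'   one more than the lags fitted).
#' @return list with the [isotonic_estimate()] (\code{estimate}), the
#'   Phillies \code{fit}, the per-condition \code{deff} table and the intact
#'   [fit_deff()] estimate.
#' @export
estimate_rheology_method <- function(track_table, n_points = 10, d0 = 13.56,
                                     fit_space = c("log", "linear"),
                                     min_frames = 11) {
  fit_space <- match.arg(fit_space)
  baseline <- .baseline_of(track_table)
  intact <- track_table[!track_table$is_protoplast, ]
  proto <- track_table[track_table$is_protoplast, ]
  if (!nrow(intact)) stop("no intact-cell tracks: cannot set the matching target")
  if (!nrow(proto)) stop("no protoplast tracks to fit")
  keep_cols <- c("track_id", "frame", "t_s", "x_um", "y_um")
  groups <- split(proto[keep_cols], proto$sorbitol_mol_per_L)
  per_cond <- lapply(groups, .deff_of_group, n_points = n_points,
                     min_frames = min_frames)
  deff_tab <- data.frame(
    sorbitol_mol_per_L = as.numeric(names(per_cond)),
    d_eff = vapply(per_cond, function(z) z$d_eff, numeric(1)),
    sem = vapply(per_cond, function(z) z$sem, numeric(1)),
    n_tracks = vapply(per_cond, function(z) z$n_tracks, numeric(1)))
  fit <- fit_phillies(deff_tab, c0_medium = baseline, d0 = d0,
                      fit_space = fit_space)
  d_int <- .deff_of_group(intact, n_points, min_frames)
  est <- invert_phillies(fit, d_int)
  list(estimate = est, fit = fit, deff = deff_tab, intact = d_int)
}

#' Run the full turgor-pressure pipeline
#'
#' Executes whichever of the three methods have inputs, converts each
#' isotonic concentration to pressure with the Van't Hoff relation, and adds
#' the cross-method average row (mean, with the SD across methods as error)
#' when at least two methods ran.
#'
#' @param volume,intensity,tracks data.frames in the respective schemas (any
#'   subset, at least one), or a [read_study_config()] object passed as
#'   \code{config}.
#' @param config optional \code{"study_config"}; its tables and options are
#'   read and used unless overridden.
#' @param temperature study temperature in kelvin (default 303.15 K).
#' @param statistic,pooled volume-method options.
#' @param intensity_window_opt,k intensity-method window options.
#' @param msd_n_points,d0,phillies_space,min_frames rheology-method options.
#' @return an object of class \code{"turgor_report"}: a per-method table of
#'   isotonic concentrations and pressures with errors, plus the average row.
#' @export
run_pipeline <- function(volume = NULL, intensity = NULL, tracks = NULL,
                         config = NULL, temperature = 303.15,
                         statistic = "median", pooled = FALSE,
                         intensity_window_opt = "bracket", k = 3,
                         msd_n_points = 10, d0 = 13.56,
                         phillies_space = "log", min_frames = 11) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "study_config"))
    if (is.null(volume) && !is.null(config$volume_table))
      volume <- read_volume_table(config$volume_table)
    if (is.null(intensity) && !is.null(config$intensity_table))
      intensity <- read_intensity_table(config$intensity_table)
    if (is.null(tracks) && !is.null(config$track_table))
      tracks <- read_track_table(config$track_table,
        frame_interval = if (is.null(config$frame_interval_s)) 0.01
                         else config$frame_interval_s)
    if (!is.null(config$temperature_K)) temperature <- config$temperature_K
    if (!is.null(config$statistic)) statistic <- config$statistic
    if (!is.null(config$intensity_window_k)) k <- config$intensity_window_k
    if (!is.null(config$msd_n_points)) msd_n_points <- config$msd_n_points
    if (!is.null(config$phillies_d0)) d0 <- config$phillies_d0
    if (!is.null(config$phillies_fit_space))
      phillies_space <- config$phillies_fit_space
  }
  if (is.null(volume) && is.null(intensity) && is.null(tracks))
    stop("no method inputs supplied: need at least one table")
  methods <- list()
  details <- list()
  if (!is.null(volume)) {
    res <- estimate_volume_method(volume, statistic = statistic,
                                  pooled = pooled)
    methods$volume <- res$estimate; details$volume <- res
  }
  if (!is.null(intensity)) {
    res <- estimate_intensity_method(intensity,
                                     window = intensity_window_opt, k = k)
    methods$intensity <- res$estimate; details$intensity <- res
  }
  if (!is.null(tracks)) {
    res <- estimate_rheology_method(tracks, n_points = msd_n_points, d0 = d0,
                                    fit_space = phillies_space,
                                    min_frames = min_frames)
    methods$rheology <- res$estimate; details$rheology <- res
  }
  rows <- lapply(methods, function(est) {
    tr <- turgor_from_isotonic(est, temperature)
    data.frame(method = est$method, c_iso = est$c_iso,
               c_iso_err = est$c_iso_err, n = est$n,
               pressure_MPa = tr$pressure_MPa,
               pressure_err_MPa = tr$pressure_err_MPa)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (nrow(tab) >= 2L) {
    avg <- combine_methods(tab$pressure_MPa)
    tab <- rbind(tab, data.frame(
      method = "average", c_iso = mean(tab$c_iso),
      c_iso_err = stats::sd(tab$c_iso), n = NA_real_,
      pressure_MPa = avg$pressure_MPa,
      pressure_err_MPa = avg$pressure_err_MPa))
  } else {
    message("single method available: average row omitted")
  }
  structure(list(table = tab, temperature = temperature, details = details),
            class = "turgor_report")
}

#' @export
print.turgor_report <- function(x, ...) {
  cat(sprintf("Turgor pressure report (T = %.2f K)\n\n", x$temperature))
  tab <- x$table
  cat(sprintf("  %-10s %-22s %-18s %s\n", "method", "c_iso (mol/L)",
              "P (MPa)", "n"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-10s %-22s %-18s %s\n", tab$method[i],
                sprintf("%.2f +/- %.2f", tab$c_iso[i], tab$c_iso_err[i]),
                sprintf("%.3g +/- %.1g", tab$pressure_MPa[i],
                        tab$pressure_err_MPa[i]),
                ifelse(is.na(tab$n[i]), "", format(tab$n[i]))))
  }
  invisible(x)
}

#' @export
as.data.frame.turgor_report <- function(x, ...) x$table

#' Write a turgor report
#'
#' @param report a [run_pipeline()] result.
#' @param json path for the machine-readable JSON report (optional).
#' @param markdown path for a human-readable Markdown table (optional).
#' @return the report, invisibly.
#' @export
write_report <- function(report, json = NULL, markdown = NULL) {
  stopifnot(inherits(report, "turgor_report"))
  tab <- report$table
  if (!is.null(json))
    jsonlite::write_json(list(temperature_K = report$temperature,
                              results = tab),
                         json, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(markdown)) {
    lines <- c(
      "| method | c_iso (mol/L) | P (MPa) | n |",
      "|---|---|---|---|",
      sprintf("| %s | %.2f ± %.2f | %.2g ± %.1g | %s |", tab$method,
              tab$c_iso, tab$c_iso_err, tab$pressure_MPa,
              tab$pressure_err_MPa,
              ifelse(is.na(tab$n), "", format(tab$n))))
    writeLines(lines, markdown)
  }
  invisible(report)
}
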