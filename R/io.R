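# Readers/writers for the three tabular schemas. Files are CSV (default) or
# TSV (by .tsv/.txt extension); all units are fixed by the schema: mol/L,
# um^3, um, s. Malformed rows are rejected with line-numbered messages rather
# than failing the whole file; structural problems (missing columns, mixed
# frame intervals within a track) are errors.

.table_sep <- function(path)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","

.read_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = .table_sep(path),
                    stringsAsFactors = FALSE)
}

.require_cols <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(what, " table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
}

# drop rows failing `bad` (logical), reporting 1-based data line numbers
# (header is line 1)
.reject_rows <- function(df, bad, why) {
  if (any(bad)) {
    message(sum(bad), " row(s) rejected (", why, "): lines ",
            paste(utils::head(which(bad) + 1L, 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "")
    df <- df[!bad, , drop = FALSE]
  }
  df
}

.check_condition_cols <- function(df) {
  bad <- !is.finite(df$sorbitol_mol_per_L) | df$sorbitol_mol_per_L < 0 |
    !is.finite(df$medium_baseline_mol_per_L) | df$medium_baseline_mol_per_L < 0
  .reject_rows(df, bad, "invalid concentration")
}

#' Read a per-cell volume table
#'
#' @param path CSV/TSV file with columns \code{strain}, \code{replicate},
#'   \code{is_protoplast}, \code{sorbitol_mol_per_L},
#'   \code{medium_baseline_mol_per_L}, \code{cell_id}, \code{volume_um3}.
#' @return validated data.frame; rows with non-positive or non-finite volumes
#'   or invalid concentrations are rejected with a message.
#' @export
read_volume_table <- function(path) {
  df <- .read_raw(path)
  .require_cols(df, c("strain", "replicate", "is_protoplast",
                      "sorbitol_mol_per_L", "medium_baseline_mol_per_L",
                      "cell_id", "volume_um3"), "volume")
  df$is_protoplast <- as.logical(df$is_protoplast)
  df <- .reject_rows(df, !is.finite(df$volume_um3) | df$volume_um3 <= 0,
                     "non-positive volume")
  .check_condition_cols(df)
}

#' Read a per-cell intensity table
#'
#' @param path CSV/TSV file with columns as in [read_volume_table()] plus
#'   \code{slide_id}, \code{roi_mean}, \code{background_mean}.
#' @return validated data.frame.
#' @export
read_intensity_table <- function(path) {
  df <- .read_raw(path)
  .require_cols(df, c("strain", "replicate", "slide_id", "is_protoplast",
                      "sorbitol_mol_per_L", "medium_baseline_mol_per_L",
                      "cell_id", "roi_mean", "background_mean"), "intensity")
  df$is_protoplast <- as.logical(df$is_protoplast)
  df <- .reject_rows(df, !is.finite(df$roi_mean) |
                       !is.finite(df$background_mean) |
                       df$background_mean < 0,
                     "invalid intensity")
  .check_condition_cols(df)
}

#' Read a particle-track table
#'
#' @param path CSV/TSV file with columns as in [read_volume_table()] plus
#'   \code{track_id}, \code{frame}, \code{t_s}, \code{x_um}, \code{y_um}.
#' @param frame_interval expected frame interval in seconds (default 0.01,
#'   100 fps); inferred intervals are validated against it.
#' @param tol relative tolerance for the interval check.
#' @return validated data.frame ordered by track and frame.
#' @export
read_track_table <- function(path, frame_interval = 0.01, tol = 1e-3) {
  df <- .read_raw(path)
  .require_cols(df, c("strain", "replicate", "is_protoplast",
                      "sorbitol_mol_per_L", "medium_baseline_mol_per_L",
                      "track_id", "frame", "t_s", "x_um", "y_um"), "track")
  df$is_protoplast <- as.logical(df$is_protoplast)
  df <- .reject_rows(df, !is.finite(df$x_um) | !is.finite(df$y_um) |
                       !is.finite(df$t_s), "non-finite coordinates")
  df <- .check_condition_cols(df)
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  dt <- diff(df$t_s)
  same_track <- df$track_id[-1L] == df$track_id[-nrow(df)]
  dt <- dt[same_track]
  if (length(dt)) {
    if (any(dt <= 0)) stop("track times are not strictly increasing")
    if (max(abs(dt - frame_interval)) > tol * frame_interval)
      stop(sprintf(
        "mixed or unexpected frame intervals (expected %g s, saw %g-%g s)",
        frame_interval, min(dt), max(dt)))
  }
  df
}

.format_numeric <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Write a table in the package's CSV/TSV schema
#'
#' Doubles are written with 17 significant digits so a write/read round trip
#' preserves values bit-exactly.
#'
#' @param df data.frame in one of the three schemas.
#' @param path output path; a .tsv/.txt extension selects tab separation.
#' @return \code{path}, invisibly.
#' @export
write_measurement_table <- function(df, path) {
  utils::write.table(.format_numeric(df), path, sep = .table_sep(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a study configuration file
#'
#' A plain keyed YAML file with input table paths and method options:
#' \code{volume_table}, \code{intensity_table}, \code{track_table} (any
#' subset), and optionally \code{temperature_K}, \code{statistic},
#' \code{intensity_window_k}, \code{msd_n_points}, \code{phillies_d0},
#' \code{phillies_fit_space}, \code{frame_interval_s}, \code{geometry}
#' (per-strain \code{radius_um}, \code{thickness_nm}, \code{strain}).
#' Relative table paths are resolved against the config file's directory.
#'
#' @param path YAML file.
#' @return a list of class \code{"study_config"}.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("volume_table", "intensity_table", "track_table")) {
    if (!is.null(cfg[[key]])) {
      p <- cfg[[key]]
      if (!file.exists(p)) p <- file.path(base, cfg[[key]])
      if (!file.exists(p)) stop("configured file not found: ", cfg[[key]])
      cfg[[key]] <- p
    }
  }
  structure(cfg, class = "study_config")
}
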