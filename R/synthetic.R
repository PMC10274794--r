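#' Define a synthetic study scenario
#'
#' A scenario bundles the ground truth and design of a simulated
#' protoplast-osmometer study; the three generators draw seeded datasets with
#' the statistical structure each estimation method assumes, so that the full
#' pipelines can be validated by parameter recovery.
#'
#' The governing laws are exact in expectation: protoplast median volume
#' follows V = m0/C_total + b0 with m0 chosen so that the isotonic sorbitol
#' concentration equals \code{isotonic_sorbitol}; corrected fluorescence is
#' proportional to 1/volume with slide-level gain and additive background;
#' cytGEMs tracks are 2D Brownian walks whose diffusion follows the Phillies
#' law D0 exp(-beta (C + C0)).
#'
#' @param strain_label identifier carried into the tables.
#' @param isotonic_sorbitol ground-truth isotonic sorbitol concentration,
#'   mol/L (the quantity every pipeline should recover).
#' @param medium_baseline_conc growth-medium osmolarity C0, mol/L.
#' @param sorbitol_grid added sorbitol concentrations of the protoplast
#'   conditions, mol/L; should span the isotonic truth.
#' @param n_cells_per_condition protoplast cells per condition per replicate.
#' @param n_intact_cells intact (reference) cells per replicate; the
#'   calibration population is sampled more deeply than each condition since
#'   all three methods invert at it.
#' @param n_replicates experimental replicates (slides).
#' @param intact_median_volume median intact-cell volume, um^3.
#' @param nonosmotic_volume non-osmotic volume b0, um^3.
#' @param volume_noise_cv cell-to-cell lognormal CV of volume.
#' @param intensity_scale corrected fluorescence (a.u.) of an intact-volume
#'   cell before slide gain.
#' @param intensity_background additive background level, a.u.
#' @param slide_factors multiplicative gain per replicate slide; default
#'   spreads 0.8--1.2.
#' @param phillies_beta crowding sensitivity beta, L/mol.
#' @param d0 dilute-limit diffusion of the 40-nm tracer, um^2/s.
#' @param n_tracks_per_condition tracks per condition (split over replicates).
#' @param frames_per_track frames per track.
#' @param frame_interval_s frame interval, s (100 fps by default).
#' @param localization_noise_sd per-axis localization error SD, um.
#' @param seed RNG seed; generators are bit-reproducible given the scenario.
#' @return an object of class \code{"study_scenario"}.
#' @export
study_scenario <- function(strain_label = "synthetic_pombe",
                           isotonic_sorbitol = 0.40,
                           medium_baseline_conc = 0.20,
                           sorbitol_grid = c(0.10, 0.25, 0.40, 0.55, 0.70, 0.85),
                           n_cells_per_condition = 100,
                           n_intact_cells = 500,
                           n_replicates = 2,
                           intact_median_volume = 100,
                           nonosmotic_volume = 15,
                           volume_noise_cv = 0.25,
                           intensity_scale = 500,
                           intensity_background = 100,
                           slide_factors = NULL,
                           phillies_beta = 5.6,
                           d0 = 13.56,
                           n_tracks_per_condition = 1000,
                           frames_per_track = 500,
                           frame_interval_s = 0.01,
                           localization_noise_sd = 0.03,
                           seed = 1L) {
  if (isotonic_sorbitol < 0 || medium_baseline_conc < 0)
    stop("concentrations must be non-negative")
  if (any(sorbitol_grid < 0)) stop("sorbitol grid must be non-negative")
  if (intact_median_volume <= nonosmotic_volume)
    stop("intact volume must exceed the non-osmotic volume")
  if (volume_noise_cv < 0 || localization_noise_sd < 0)
    stop("noise parameters must be non-negative")
  if (is.null(slide_factors))
    slide_factors <- exp(seq(log(0.8), log(1.2),
                             length.out = n_replicates))
  stopifnot(length(slide_factors) == n_replicates, all(slide_factors > 0))
  if (isotonic_sorbitol < min(sorbitol_grid) ||
      isotonic_sorbitol > max(sorbitol_grid))
    warning("sorbitol grid does not span the isotonic truth; inversions will extrapolate")
  sc <- list(strain_label = strain_label,
             isotonic_sorbitol = isotonic_sorbitol,
             medium_baseline_conc = medium_baseline_conc,
             sorbitol_grid = sorbitol_grid,
             n_cells_per_condition = as.integer(n_cells_per_condition),
             n_intact_cells = as.integer(n_intact_cells),
             n_replicates = as.integer(n_replicates),
             intact_median_volume = intact_median_volume,
             nonosmotic_volume = nonosmotic_volume,
             volume_noise_cv = volume_noise_cv,
             intensity_scale = intensity_scale,
             intensity_background = intensity_background,
             slide_factors = slide_factors,
             phillies_beta = phillies_beta,
             d0 = d0,
             n_tracks_per_condition = as.integer(n_tracks_per_condition),
             frames_per_track = as.integer(frames_per_track),
             frame_interval_s = frame_interval_s,
             localization_noise_sd = localization_noise_sd,
             seed = as.integer(seed))
  # slope of the osmometer law placing the isotonic point at the truth
  sc$m0 <- (isotonic_sorbitol + medium_baseline_conc) *
    (intact_median_volume - nonosmotic_volume)
  structure(sc, class = "study_scenario")
}

#' @export
print.study_scenario <- function(x, ...) {
  cat(sprintf("Synthetic study scenario '%s'\n", x$strain_label))
  cat(sprintf("  isotonic sorbitol truth: %.2f mol/L (medium baseline %.2f)\n",
              x$isotonic_sorbitol, x$medium_baseline_conc))
  cat(sprintf("  grid: %s mol/L; %d replicates; seed %d\n",
              paste(format(x$sorbitol_grid), collapse = ", "),
              x$n_replicates, x$seed))
  invisible(x)
}

# median-preserving lognormal draw: median(V) = med exactly in expectation
.rlnorm_median <- function(n, med, cv) {
  if (cv == 0) return(rep(med, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
}

# expected protoplast median volume at added sorbitol C
.true_volume <- function(scenario, sorbitol)
  scenario$m0 / (sorbitol + scenario$medium_baseline_conc) +
    scenario$nonosmotic_volume

#' Generate a synthetic per-cell volume table
#'
#' Intact cells are drawn lognormal around the scenario's intact median;
#' protoplast populations at each sorbitol condition are drawn lognormal
#' around the osmometer-law median V = m0/C_total + b0. At zero CV the law is
#' exact and the downstream fit recovers (m0, b0) to machine precision.
#'
#' @param scenario a [study_scenario()].
#' @return data.frame in the volume-table schema (\code{strain},
#'   \code{replicate}, \code{is_protoplast}, \code{sorbitol_mol_per_L},
#'   \code{medium_baseline_mol_per_L}, \code{cell_id}, \code{volume_um3}).
#' @export
gen_volume_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "study_scenario"))
  set.seed(scenario$seed)
  rows <- list()
  for (rep_i in seq_len(scenario$n_replicates)) {
    v_int <- .rlnorm_median(scenario$n_intact_cells,
                            scenario$intact_median_volume,
                            scenario$volume_noise_cv)
    rows[[length(rows) + 1L]] <- data.frame(
      strain = scenario$strain_label, replicate = rep_i,
      is_protoplast = FALSE, sorbitol_mol_per_L = 0,
      medium_baseline_mol_per_L = scenario$medium_baseline_conc,
      cell_id = sprintf("int_r%d_c%04d", rep_i,
                        seq_len(scenario$n_intact_cells)),
      volume_um3 = v_int)
    for (conc in scenario$sorbitol_grid) {
      v <- .rlnorm_median(scenario$n_cells_per_condition,
                          .true_volume(scenario, conc),
                          scenario$volume_noise_cv)
      rows[[length(rows) + 1L]] <- data.frame(
        strain = scenario$strain_label, replicate = rep_i,
        is_protoplast = TRUE, sorbitol_mol_per_L = conc,
        medium_baseline_mol_per_L = scenario$medium_baseline_conc,
        cell_id = sprintf("pro_r%d_s%.2f_c%04d", rep_i, conc,
                          seq_len(scenario$n_cells_per_condition)),
        volume_um3 = v)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic per-cell intensity table
#'
#' Each cell carries a fixed amount of cytoplasmic fluorophore, so its
#' corrected intensity is proportional to 1/volume; volumes are drawn as in
#' [gen_volume_dataset()]. Raw ROI means add a slide-level multiplicative gain
#' and an additive background; an intact calibration population is present on
#' every slide (one slide per replicate).
#'
#' @param scenario a [study_scenario()].
#' @return data.frame in the intensity-table schema (adds \code{slide_id},
#'   \code{roi_mean}, \code{background_mean}).
#' @export
gen_intensity_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "study_scenario"))
  set.seed(scenario$seed + 1L)
  bg <- scenario$intensity_background
  rows <- list()
  for (rep_i in seq_len(scenario$n_replicates)) {
    gain <- scenario$slide_factors[rep_i]
    slide <- sprintf("slide_%02d", rep_i)
    make <- function(volumes, is_proto, conc, prefix) {
      corrected <- scenario$intensity_scale *
        scenario$intact_median_volume / volumes
      data.frame(
        strain = scenario$strain_label, replicate = rep_i,
        slide_id = slide, is_protoplast = is_proto,
        sorbitol_mol_per_L = conc,
        medium_baseline_mol_per_L = scenario$medium_baseline_conc,
        cell_id = sprintf("%s_r%d_s%.2f_c%04d", prefix, rep_i, conc,
                          seq_along(volumes)),
        roi_mean = gain * corrected + bg, background_mean = bg)
    }
    v_int <- .rlnorm_median(scenario$n_intact_cells,
                            scenario$intact_median_volume,
                            scenario$volume_noise_cv)
    rows[[length(rows) + 1L]] <- make(v_int, FALSE, 0, "int")
    for (conc in scenario$sorbitol_grid) {
      v <- .rlnorm_median(scenario$n_cells_per_condition,
                          .true_volume(scenario, conc),
                          scenario$volume_noise_cv)
      rows[[length(rows) + 1L]] <- make(v, TRUE, conc, "pro")
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic cytGEMs tracks
#'
#' 2D Gaussian random walks at 100 fps with per-step variance 2 D dt per
#' axis plus independent localization noise on every position. Protoplast
#' conditions diffuse at D = D0 exp(-beta (C + C0)); intact-cell tracks use
#' the D corresponding to the scenario's isotonic truth, so matching
#' mobilities recovers that truth.
#'
#' @param scenario a [study_scenario()].
#' @return data.frame in the track-table schema (\code{track_id},
#'   \code{frame}, \code{t_s}, \code{x_um}, \code{y_um} plus condition
#'   columns).
#' @export
gen_brownian_tracks <- function(scenario) {
  stopifnot(inherits(scenario, "study_scenario"))
  set.seed(scenario$seed + 2L)
  dt <- scenario$frame_interval_s
  nf <- scenario$frames_per_track
  conds <- data.frame(
    conc = c(scenario$sorbitol_grid, scenario$isotonic_sorbitol),
    is_protoplast = c(rep(TRUE, length(scenario$sorbitol_grid)), FALSE))
  rows <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    d_true <- scenario$d0 *
      exp(-scenario$phillies_beta *
            (conds$conc[i] + scenario$medium_baseline_conc))
    nt <- scenario$n_tracks_per_condition
    step_sd <- sqrt(2 * d_true * dt)
    x <- apply(matrix(stats::rnorm(nf * nt, sd = step_sd), nf, nt), 2, cumsum)
    y <- apply(matrix(stats::rnorm(nf * nt, sd = step_sd), nf, nt), 2, cumsum)
    if (scenario$localization_noise_sd > 0) {
      x <- x + stats::rnorm(nf * nt, sd = scenario$localization_noise_sd)
      y <- y + stats::rnorm(nf * nt, sd = scenario$localization_noise_sd)
    }
    sorb <- if (conds$is_protoplast[i]) conds$conc[i] else 0
    rows[[i]] <- data.frame(
      strain = scenario$strain_label,
      replicate = rep(rep(seq_len(scenario$n_replicates), length.out = nt),
                      each = nf),
      is_protoplast = conds$is_protoplast[i],
      sorbitol_mol_per_L = sorb,
      medium_baseline_mol_per_L = scenario$medium_baseline_conc,
      track_id = rep(sprintf("trk_%s_%.2f_%05d",
                             if (conds$is_protoplast[i]) "pro" else "int",
                             conds$conc[i], seq_len(nt)), each = nf),
      frame = rep(seq_len(nf), nt),
      t_s = rep((seq_len(nf) - 1L) * dt, nt),
      x_um = as.vector(x), y_um = as.vector(y))
  }
  do.call(rbind, rows)
}
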