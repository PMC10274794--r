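# Fixtures built in code: exact (noise-free) tables obeying each governing
# law, and a small-but-noisy scenario for fast pipeline tests.

# volume table lying exactly on V = m0/C_total + b0
exact_volume_table <- function(m0 = 30, b0 = 20,
                               sorbitol = c(0.2, 0.7, 1.2),
                               baseline = 0.3, n_reps = 2) {
  grid <- expand.grid(sorbitol_mol_per_L = sorbitol,
                      replicate = seq_len(n_reps))
  data.frame(strain = "exact", replicate = grid$replicate,
             is_protoplast = TRUE,
             sorbitol_mol_per_L = grid$sorbitol_mol_per_L,
             medium_baseline_mol_per_L = baseline,
             cell_id = sprintf("c%03d", seq_len(nrow(grid))),
             volume_um3 = m0 / (grid$sorbitol_mol_per_L + baseline) + b0)
}

# small noisy scenario: fast enough for io/pipeline round trips
small_scenario <- function(seed = 42, ...) {
  study_scenario(n_cells_per_condition = 30, n_intact_cells = 50,
                 n_tracks_per_condition = 40, frames_per_track = 60,
                 seed = seed, ...)
}

# straight-line 2D track with speed v (um/s), for the ballistic closed form
ballistic_track <- function(v = 2, n = 30, dt = 0.01, angle = 0.7) {
  tt <- (seq_len(n) - 1) * dt
  data.frame(t_s = tt, x_um = v * tt * cos(angle), y_um = v * tt * sin(angle))
}

# raw Brownian ensemble as frames x tracks matrices (independent of the
# package's generator; used as the closed-form oracle for MSD/D_eff)
brownian_matrices <- function(d_true, n_tracks, n_frames, dt = 0.01,
                              loc_sd = 0) {
  step <- sqrt(2 * d_true * dt)
  x <- apply(matrix(rnorm(n_frames * n_tracks, sd = step),
                    n_frames, n_tracks), 2, cumsum)
  y <- apply(matrix(rnorm(n_frames * n_tracks, sd = step),
                    n_frames, n_tracks), 2, cumsum)
  if (loc_sd > 0) {
    x <- x + rnorm(length(x), sd = loc_sd)
    y <- y + rnorm(length(y), sd = loc_sd)
  }
  list(x = x, y = y, dt = dt)
}
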