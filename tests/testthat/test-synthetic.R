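test_that("generators are bit-reproducible under a fixed seed", {
  sc <- small_scenario(seed = 77)
  expect_identical(gen_volume_dataset(sc), gen_volume_dataset(sc))
  expect_identical(gen_intensity_dataset(sc), gen_intensity_dataset(sc))
  expect_identical(gen_brownian_tracks(sc), gen_brownian_tracks(sc))
  sc2 <- small_scenario(seed = 78)
  expect_false(identical(gen_volume_dataset(sc)$volume_um3,
                         gen_volume_dataset(sc2)$volume_um3))
})

test_that("scenario validation catches unusable designs", {
  expect_error(study_scenario(isotonic_sorbitol = -1), "non-negative")
  expect_error(study_scenario(intact_median_volume = 10,
                              nonosmotic_volume = 15), "exceed")
  expect_warning(study_scenario(sorbitol_grid = c(0.6, 0.8, 1.0)), "span")
})

test_that("zero-noise volumes sit exactly on the osmometer law", {
  sc <- small_scenario(volume_noise_cv = 0)
  fit <- fit_bvh(gen_volume_dataset(sc))
  expect_equal(fit$m0, sc$m0, tolerance = 1e-9)
  expect_equal(fit$b0, sc$nonosmotic_volume, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("zero-noise intensities follow the inverse-volume law exactly", {
  truth <- 0.40
  half_volume_conc <- NULL
  sc <- study_scenario(isotonic_sorbitol = truth, volume_noise_cv = 0,
                       sorbitol_grid = c(0.1, 0.25, truth, 0.55, 1.2571),
                       n_cells_per_condition = 10, n_intact_cells = 10,
                       slide_factors = c(1, 1), seed = 1)
  res <- estimate_intensity_method(gen_intensity_dataset(sc), window = "all")
  means <- aggregate(normalized ~ sorbitol_mol_per_L, res$normalized, mean)
  at_iso <- means$normalized[means$sorbitol_mol_per_L == truth]
  expect_equal(at_iso, 1.0, tolerance = 1e-9)
  # condition whose true volume is half the intact volume -> normalized 2
  v_half <- means$normalized[means$sorbitol_mol_per_L == 1.2571]
  v_true <- sc$m0 / (1.2571 + sc$medium_baseline_conc) + sc$nonosmotic_volume
  expect_equal(v_true, sc$intact_median_volume / 2, tolerance = 1e-3)
  expect_equal(v_half, 2.0, tolerance = 1e-3)
})

test_that("zero-diffusion, zero-noise tracks are stationary", {
  sc <- study_scenario(d0 = 0, localization_noise_sd = 0,
                       n_tracks_per_condition = 1, frames_per_track = 20,
                       seed = 2)
  trk <- gen_brownian_tracks(sc)
  expect_true(all(trk$x_um == 0) && all(trk$y_um == 0))
})

test_that("generated tracks diffuse at the Phillies-law rate", {
  sc <- study_scenario(n_tracks_per_condition = 400, frames_per_track = 200,
                       localization_noise_sd = 0, seed = 6,
                       sorbitol_grid = c(0.1, 0.4, 0.8))
  trk <- gen_brownian_tracks(sc)
  one <- trk[trk$is_protoplast & trk$sorbitol_mol_per_L == 0.4, ]
  est <- osmometry:::.deff_of_group(one, n_points = 10, min_frames = 11)
  d_true <- sc$d0 * exp(-sc$phillies_beta * (0.4 + sc$medium_baseline_conc))
  expect_lt(abs(est$d_eff - d_true), 3 * est$sem)
})

test_that("each pipeline converges to the scenario truth as noise vanishes", {
  sc_v <- small_scenario(volume_noise_cv = 0)
  est_v <- estimate_volume_method(gen_volume_dataset(sc_v))$estimate
  expect_equal(est_v$c_iso, sc_v$isotonic_sorbitol, tolerance = 1e-9)
  sc_i <- study_scenario(volume_noise_cv = 0, slide_factors = c(0.8, 1.2),
                         n_cells_per_condition = 10, n_intact_cells = 10,
                         isotonic_sorbitol = 0.37, seed = 3)
  est_i <- estimate_intensity_method(gen_intensity_dataset(sc_i),
                                     window = "bracket", k = 2)$estimate
  # with k = 2 the window brackets the truth tightly; curvature of the
  # inverse-volume law leaves a small residual even without noise
  expect_equal(est_i$c_iso, sc_i$isotonic_sorbitol, tolerance = 0.02)
  sc_r <- study_scenario(localization_noise_sd = 0,
                         n_tracks_per_condition = 600,
                         frames_per_track = 300, isotonic_sorbitol = 0.43,
                         seed = 4)
  est_r <- estimate_rheology_method(gen_brownian_tracks(sc_r))$estimate
  expect_equal(est_r$c_iso, sc_r$isotonic_sorbitol, tolerance = 0.02)
})
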