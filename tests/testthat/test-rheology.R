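test_that("MSD of stationary and ballistic tracks matches closed forms", {
  still <- data.frame(t_s = (0:20) * 0.01, x_um = 1.3, y_um = -0.4)
  expect_equal(compute_msd(still)$msd, rep(0, 10))
  v <- 2.5
  bal <- ballistic_track(v = v, n = 40)
  curve <- compute_msd(bal)
  expect_equal(curve$msd, (v * curve$lags)^2, tolerance = 1e-10)
  expect_error(compute_msd(ballistic_track(n = 8)), "short")
  expect_error(compute_msd(data.frame(t_s = c(0, 0.01, 0.015, 0.02, 0.04,
                                              0.05, 0.06, 0.07, 0.08, 0.09,
                                              0.10, 0.11),
                                      x_um = 0, y_um = 0)), "uniform")
})

test_that("MSD is invariant under translation and rotation", {
  set.seed(4)
  mats <- brownian_matrices(0.3, 1, 50)
  trk <- data.frame(t_s = (0:49) * 0.01, x_um = mats$x[, 1], y_um = mats$y[, 1])
  base <- compute_msd(trk)$msd
  shifted <- transform(trk, x_um = x_um + 5, y_um = y_um - 2)
  th <- 0.8
  rotated <- transform(trk, x_um = cos(th) * x_um - sin(th) * y_um,
                       y_um = sin(th) * x_um + cos(th) * y_um)
  expect_equal(compute_msd(shifted)$msd, base, tolerance = 1e-12)
  expect_equal(compute_msd(rotated)$msd, base, tolerance = 1e-12)
})

test_that("the diffusion fit is exact and linear on ideal curves", {
  lags <- 0.01 * (1:10)
  mk <- function(d) structure(list(lags = lags, msd = 4 * d * lags,
                                   n_pairs = rep(100, 10),
                                   sem = rep(0, 10)), class = "msd_curve")
  expect_equal(fit_deff(list(mk(0.36)))$d_eff, 0.36, tolerance = 1e-12)
  one <- fit_deff(list(mk(0.5)))$d_eff
  two <- fit_deff(list(structure(list(lags = lags, msd = 2 * 4 * 0.5 * lags,
                                      n_pairs = rep(100, 10),
                                      sem = rep(0, 10)),
                                 class = "msd_curve")))$d_eff
  expect_equal(two, 2 * one, tolerance = 1e-12)
  set.seed(8)
  for (d in runif(5, 0.05, 2))
    expect_equal(fit_deff(list(mk(d)))$d_eff, d, tolerance = 1e-12)
  expect_error(fit_deff(list()), "no MSD curves")
})

test_that("ensemble MSD and fitted D match Brownian theory within 3 SEM", {
  set.seed(15)
  d_true <- 0.40
  mats <- brownian_matrices(d_true, n_tracks = 1000, n_frames = 500)
  tt <- (seq_len(500) - 1) * mats$dt
  curves <- lapply(seq_len(40), function(j)
    compute_msd(data.frame(t_s = tt, x_um = mats$x[, j], y_um = mats$y[, j])))
  msd <- osmometry:::.msd_matrix(mats$x, mats$y, 10)
  est <- fit_deff(msd, lags = mats$dt * (1:10))
  # per-lag ensemble MSD vs 4 D tau
  lagmean <- rowMeans(msd)
  lagsem <- apply(msd, 1, sd) / sqrt(ncol(msd))
  expect_true(all(abs(lagmean - 4 * d_true * mats$dt * (1:10)) < 3 * lagsem))
  expect_lt(abs(est$d_eff - d_true), 3 * est$sem)
  # matrix fast path agrees with per-curve path
  est_curves <- fit_deff(curves)
  est_sub <- fit_deff(msd[, 1:40], lags = mats$dt * (1:10))
  expect_equal(est_curves$d_eff, est_sub$d_eff, tolerance = 1e-12)
})

test_that("Phillies fit recovers beta exactly from model-generated points", {
  beta <- 3.0; c0 <- 0.3
  conc <- c(0.1, 0.3, 0.5, 0.8)
  d <- 13.56 * exp(-beta * (conc + c0))
  expect_equal(d[1], 4.084, tolerance = 1e-3)
  fit <- fit_phillies(data.frame(sorbitol_mol_per_L = conc, d_eff = d),
                      c0_medium = c0)
  expect_equal(fit$beta, beta, tolerance = 1e-12)
  linfit <- fit_phillies(data.frame(sorbitol_mol_per_L = conc, d_eff = d),
                         c0_medium = c0, fit_space = "linear")
  expect_equal(linfit$beta, beta, tolerance = 1e-6)
  expect_error(fit_phillies(data.frame(sorbitol_mol_per_L = 0.1,
                                       d_eff = 4), c0_medium = 0.3),
               "distinct")
  expect_error(fit_phillies(data.frame(sorbitol_mol_per_L = conc,
                                       d_eff = rep(14, 4)), c0_medium = 0.3),
               "unphysical")
})

test_that("reported beta uncertainty covers the truth on noisy data", {
  set.seed(23)
  beta <- 5.6; c0 <- 0.2
  conc <- c(0.10, 0.25, 0.40, 0.55, 0.70, 0.85)
  hits <- vapply(1:20, function(i) {
    d <- 13.56 * exp(-beta * (conc + c0)) * exp(rnorm(6, sd = 0.05))
    fit <- fit_phillies(data.frame(sorbitol_mol_per_L = conc, d_eff = d),
                        c0_medium = c0)
    abs(fit$beta - beta) < 3 * sqrt(fit$beta_variance)
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("Phillies inversion is the exact inverse of prediction", {
  fit <- fit_phillies(
    data.frame(sorbitol_mol_per_L = c(0.1, 0.4, 0.8),
               d_eff = 13.56 * exp(-3 * (c(0.1, 0.4, 0.8) + 0.3))),
    c0_medium = 0.3)
  expect_equal(invert_phillies(fit, 13.56 * exp(-3 * 0.4))$c_iso, 0.1,
               tolerance = 1e-10)
  for (cc in c(0.05, 0.3, 0.7))
    expect_equal(invert_phillies(fit, predict(fit, cc))$c_iso, cc,
                 tolerance = 1e-10)
  # predicted diffusion decreases with concentration
  grid <- seq(0, 1, by = 0.1)
  expect_true(all(diff(predict(fit, grid)) < 0))
  expect_error(invert_phillies(fit, 20), "between 0 and d0")
  expect_error(invert_phillies(fit, 13.5), "negative")
})
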