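test_that("background correction and calibration give dimensionless concentration", {
  rec <- data.frame(slide_id = "s1", roi_mean = 1100, background_mean = 100)
  cal <- data.frame(slide_id = "s1", intact_mean = 500)
  expect_equal(normalize_intensity(rec, cal)$normalized, 2.0)
  # intact cells normalized against their own calibration average to 1
  intact <- data.frame(slide_id = "s1", roi_mean = c(400, 600, 500),
                       background_mean = 50)
  cal2 <- data.frame(slide_id = "s1",
                     intact_mean = mean(intact$roi_mean - 50))
  expect_equal(mean(normalize_intensity(intact, cal2)$normalized), 1.0)
  expect_error(normalize_intensity(
    data.frame(slide_id = "s2", roi_mean = 1, background_mean = 0), cal),
    "no calibration")
  expect_message(out <- normalize_intensity(
    data.frame(slide_id = "s1", roi_mean = c(90, 300),
               background_mean = 100), cal), "excluded")
  expect_equal(nrow(out), 1L)
})

test_that("normalization cancels any common gain applied to one slide", {
  rec <- data.frame(slide_id = "s1", roi_mean = c(700, 900),
                    background_mean = 100)
  cal <- data.frame(slide_id = "s1", intact_mean = 400)
  base <- normalize_intensity(rec, cal)$normalized
  g <- 3.7
  scaled <- normalize_intensity(
    transform(rec, roi_mean = g * roi_mean, background_mean = g * 100),
    transform(cal, intact_mean = g * 400))$normalized
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("slide factors are removed by per-slide calibration on synthetic data", {
  sc <- study_scenario(n_cells_per_condition = 400, n_intact_cells = 400,
                       slide_factors = c(0.8, 1.2), seed = 21)
  res <- estimate_intensity_method(gen_intensity_dataset(sc), window = "all")
  norm <- res$normalized
  by_slide <- tapply(norm$normalized, list(norm$slide_id,
                                           norm$sorbitol_mol_per_L), mean)
  expect_lt(max(abs(by_slide[1, ] / by_slide[2, ] - 1)), 0.06)
})

test_that("exact linear data are fitted to machine precision", {
  dat <- data.frame(sorbitol_mol_per_L = rep(c(0.1, 0.3, 0.5), each = 4),
                    normalized = 0.5 + 2.0 * rep(c(0.1, 0.3, 0.5), each = 4))
  fit <- fit_intensity(dat)
  expect_equal(unname(coef(fit)), c(0.5, 2.0), tolerance = 1e-12)
  expect_error(fit_intensity(dat, window = c(0.25, 0.35)), "distinct")
})

test_that("inversion solves the calibration line and flags extrapolation", {
  dat <- data.frame(sorbitol_mol_per_L = c(0.1, 0.3, 0.5),
                    normalized = 0.5 + 2.0 * c(0.1, 0.3, 0.5))
  fit <- fit_intensity(dat)
  est <- invert_intensity(fit, target = 1.0)
  expect_equal(est$c_iso, 0.25, tolerance = 1e-12)
  expect_null(est$note)
  expect_equal(invert_intensity(fit, target = 0.5)$c_iso, 0)
  out <- invert_intensity(fit, target = 2.0)
  expect_match(out$note, "outside")
  # round trip through predict
  for (cc in c(0.12, 0.31, 0.49))
    expect_equal(invert_intensity(fit, predict(fit, cc))$c_iso, cc,
                 tolerance = 1e-12)
})

test_that("mean normalized intensity rises with sorbitol on synthetic data", {
  sc <- study_scenario(seed = 13, n_cells_per_condition = 60,
                       n_intact_cells = 80)
  res <- estimate_intensity_method(gen_intensity_dataset(sc), window = "all")
  means <- aggregate(normalized ~ sorbitol_mol_per_L, res$normalized, mean)
  means <- means[order(means$sorbitol_mol_per_L), ]
  expect_true(all(diff(means$normalized) > 0))
  expect_gt(res$fit$slope, 0)
})

test_that("fitted slope matches generator-implied slope within 3 SE", {
  sc <- study_scenario(n_cells_per_condition = 300, n_intact_cells = 300,
                       seed = 31)
  res <- estimate_intensity_method(gen_intensity_dataset(sc), window = "all")
  fit <- res$fit
  # generator truth: normalized mean is V_intact / (m0/(C+C0) + b0);
  # reference slope is the OLS slope through the exact condition means
  f <- function(cc) sc$intact_median_volume /
    (sc$m0 / (cc + sc$medium_baseline_conc) + sc$nonosmotic_volume)
  truth <- lm(y ~ x, data.frame(x = sc$sorbitol_grid,
                                y = f(sc$sorbitol_grid)))
  expect_lt(abs(fit$slope - coef(truth)[2]),
            3 * sqrt(vcov(fit)["slope", "slope"]) + 1e-8)
})
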