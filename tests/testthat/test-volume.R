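test_that("population summaries use the requested statistic and replicate spread", {
  expect_equal(summarize_population(c(10, 20, 30))$summary, 20)
  two <- summarize_population(c(rep(100, 3), rep(104, 3)),
                              replicate = rep(1:2, each = 3))
  expect_equal(two$summary, 102)
  expect_equal(two$spread, sd(c(100, 104)))
  expect_error(summarize_population(numeric(0)), "empty")
  expect_error(summarize_population(c(10, -5)), "positive")
})

test_that("sampled lognormal population recovers the scenario median", {
  sc <- study_scenario(n_intact_cells = 4000, seed = 3)
  tab <- gen_volume_dataset(sc)
  intact <- tab[!tab$is_protoplast & tab$replicate == 1, ]
  expect_equal(median(intact$volume_um3), sc$intact_median_volume,
               tolerance = 0.02)
})

test_that("noise-free osmometer data are interpolated exactly", {
  fit <- fit_bvh(exact_volume_table(m0 = 30, b0 = 20))
  expect_equal(unname(coef(fit)), c(30, 20), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(predict(fit, 0.75), 30 / 0.75 + 20, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  tab <- exact_volume_table(sorbitol = c(0.5, 0.5, 0.5))
  expect_error(fit_bvh(tab), "distinct")
  tab2 <- exact_volume_table(sorbitol = c(0, 0.5, 1), baseline = 0)
  tab2$volume_um3[tab2$sorbitol_mol_per_L == 0] <- 50
  expect_error(fit_bvh(tab2), "osmolarity")
})

test_that("fitted parameters match generator truth within 3 SE on noisy data", {
  sc <- study_scenario(volume_noise_cv = 0.03, n_cells_per_condition = 100,
                       seed = 5)
  fit <- fit_bvh(gen_volume_dataset(sc))
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(fit$m0 - sc$m0), 3 * se["m0"])
  expect_lt(abs(fit$b0 - sc$nonosmotic_volume), 3 * se["b0"])
})

test_that("inversion solves the osmometer law and guards its domain", {
  fit <- fit_bvh(exact_volume_table(m0 = 30, b0 = 20, baseline = 0))
  est <- invert_bvh(fit, target_volume = 95, medium_baseline = 0)
  expect_equal(est$c_iso, 0.4, tolerance = 1e-10)
  expect_error(invert_bvh(fit, target_volume = 19, medium_baseline = 0),
               "non-osmotic")
  expect_error(invert_bvh(fit, target_volume = 30, medium_baseline = 5),
               "hypotonic")
})

test_that("fit -> predict -> invert is the identity on noiseless data", {
  fit <- fit_bvh(exact_volume_table(m0 = 51, b0 = 15, baseline = 0.2))
  for (cc in c(0.15, 0.4, 0.9)) {
    v <- predict(fit, cc + 0.2)
    expect_equal(invert_bvh(fit, v, 0.2)$c_iso, cc, tolerance = 1e-9)
  }
})

test_that("isotonic concentration decreases with target volume", {
  fit <- fit_bvh(exact_volume_table())
  targets <- seq(30, 120, by = 10)
  c_iso <- vapply(targets, function(v) invert_bvh(fit, v, 0)$c_iso, numeric(1))
  expect_true(all(diff(c_iso) < 0))
})

test_that("delta-method error agrees with a bootstrap oracle within 20%", {
  sc <- study_scenario(n_cells_per_condition = 50, n_intact_cells = 100,
                       seed = 9)
  tab <- gen_volume_dataset(sc)
  proto <- tab[tab$is_protoplast, ]
  fit <- fit_bvh(proto)
  target <- 100
  delta <- invert_bvh(fit, target, sc$medium_baseline_conc)$c_iso_err
  set.seed(99)
  boot <- invert_bvh(fit, target, sc$medium_baseline_conc,
                     bootstrap = TRUE, data = proto, n_boot = 400)$c_iso_err
  expect_lt(abs(boot - delta) / delta, 0.20)
})
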