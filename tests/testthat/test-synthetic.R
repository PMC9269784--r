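test_that("phantoms voxelize analytic solids faithfully", {
  ell <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(10, 5, 2.5),
                                   spacing = rep(0.5, 3)))
  dims <- bounding_box_dims(ell)
  expect_lte(abs(dims[["l"]] - 20), 0.5)
  expect_lte(abs(dims[["b"]] - 10), 0.5)
  expect_lte(abs(dims[["t"]] - 5), 0.5)

  cub <- make_phantom(phantom_spec("cuboid", semi_axes = c(10, 5, 2.5),
                                   spacing = c(1, 1, 1)))
  expect_equal(sum(cub$grid), 1000)

  sph <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(10, 10, 10),
                                   spacing = rep(0.5, 3)))
  expect_equal(voxel_volume(sph), 4 / 3 * pi * 1000, tolerance = 0.02)

  sup <- make_phantom(phantom_spec("superellipsoid", semi_axes = c(6, 6, 6),
                                   spacing = c(1, 1, 1)))
  # superellipsoid (e = 4) lies between the ellipsoid and the cuboid
  expect_gt(sum(sup$grid), sum(make_phantom(
    phantom_spec("ellipsoid", semi_axes = c(6, 6, 6),
                 spacing = c(1, 1, 1)))$grid))
  expect_lt(sum(sup$grid), 12^3)

  expect_error(make_phantom(phantom_spec("ellipsoid",
                                         semi_axes = c(0.1, 0.1, 0.1),
                                         spacing = c(1, 1, 1))),
               "degenerate")
  expect_error(phantom_spec("ellipsoid", semi_axes = c(1, -1, 1)), "positive")
})

test_that("phantom voxelization is deterministic given the spec", {
  s <- phantom_spec("ellipsoid", semi_axes = c(7, 4, 3),
                    spacing = c(0.8, 0.8, 1.2), rotation = c(0.3, 0.1, 0.2))
  expect_identical(make_phantom(s)$grid, make_phantom(s)$grid)
})

test_that("moment-matched beta hits its targets exactly and rejects infeasible ones", {
  u <- moment_matched_beta(0.5, sqrt(1 / 12))
  expect_equal(u$shape1, 1, tolerance = 1e-12)
  expect_equal(u$shape2, 1, tolerance = 1e-12)

  p <- moment_matched_beta(0.123, 0.111)
  expect_equal(p$shape1 / (p$shape1 + p$shape2), 0.123, tolerance = 1e-12)
  analytic_var <- with(p, shape1 * shape2 /
                         ((shape1 + shape2)^2 * (shape1 + shape2 + 1)))
  expect_equal(sqrt(analytic_var), 0.111, tolerance = 1e-12)

  expect_error(moment_matched_beta(0.5, 0.6), "infeasible")
  expect_error(moment_matched_beta(1.2, 0.1), "\\(0, 1\\)")
})

test_that("moment-matched lognormal hits its targets and stays positive", {
  p <- moment_matched_lognormal(2138.1, 2369.2)
  expect_equal(exp(p$meanlog + p$sdlog^2 / 2), 2138.1, tolerance = 1e-9)
  analytic_sd <- sqrt((exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2))
  expect_equal(analytic_sd, 2369.2, tolerance = 1e-6)

  tiny <- moment_matched_lognormal(50, 50e-6)
  set.seed(1)
  expect_equal(rlnorm(100, tiny$meanlog, tiny$sdlog), rep(50, 100),
               tolerance = 1e-5)

  set.seed(2)
  expect_true(all(rlnorm(1e4, p$meanlog, p$sdlog) > 0))
  expect_error(moment_matched_lognormal(-1, 2), "positive")
})

test_that("built-in calibrations load with the published group sizes", {
  ssr1 <- load_calibration("SSR1")
  expect_equal(ssr1$n_benign, 38L)
  expect_equal(ssr1$n_malignant, 71L)
  expect_setequal(unique(ssr1$moments$feature), feature_names())
  lungx <- load_calibration("LUNGx")
  expect_equal(lungx$n_benign, 42L)
  expect_equal(lungx$n_malignant, 41L)
  expect_error(load_calibration("nope.csv"), "not found")
})

test_that("simulated cohorts are reproducible and sized per calibration", {
  cal <- load_calibration("SSR1")
  co <- simulate_cohort(cal, seed = 4)
  expect_equal(nrow(co), 109)
  expect_equal(sum(co$label == "benign"), 38)
  expect_identical(co, simulate_cohort(cal, seed = 4))
  expect_false(identical(co$afl, simulate_cohort(cal, seed = 5)$afl))
  expect_true(all(co$volume > 0))
  dimless <- setdiff(feature_names(), c("max3ddiam", "surfarea", "volume"))
  for (f in dimless) expect_true(all(co[[f]] >= 0 & co[[f]] <= 1))
})

test_that("cohort moments converge to the calibration targets", {
  cal <- load_calibration("SSR1")
  target <- cal$moments
  means <- vapply(1:200, function(s) {
    co <- simulate_cohort(cal, seed = s)
    mean(co$afl[co$label == "benign"])
  }, numeric(1))
  tgt <- target$mean[target$feature == "afl" & target$class == "benign"]
  sd_tgt <- target$sd[target$feature == "afl" & target$class == "benign"]
  se <- sd_tgt / sqrt(200 * 38)
  expect_lt(abs(mean(means) - tgt), 4 * se)
})

test_that("geometric cohorts are internally consistent and encode flat benign lesions", {
  sim <- suppressWarnings(
    simulate_geometric_cohort(n_benign = 5, n_malignant = 5, seed = 3))
  expect_length(sim$masks, 10)
  co <- sim$cohort
  expect_equal(nrow(co), 10)
  expect_true(all(feature_names() %in% names(co)))
  expect_equal(co$ael + co$afl + co$aco, rep(1, 10), tolerance = 1e-9)

  sim2 <- suppressWarnings(
    simulate_geometric_cohort(n_benign = 12, n_malignant = 12, seed = 9))
  co2 <- sim2$cohort
  expect_gt(mean(co2$afl[co2$label == "benign"]),
            mean(co2$afl[co2$label == "malignant"]))
  expect_identical(co2, suppressWarnings(
    simulate_geometric_cohort(n_benign = 12, n_malignant = 12,
                              seed = 9))$cohort)
})
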