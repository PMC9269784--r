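test_that("bounding box uses full voxel extents scaled by spacing", {
  expect_equal(bounding_box_dims(single_voxel_mask()),
               c(l = 1, b = 1, t = 1))
  expect_equal(bounding_box_dims(solid_cuboid_mask(20, 10, 5)),
               c(l = 20, b = 10, t = 5))
  # anisotropic spacing: 10x10x4 voxels at (1.37, 1.37, 3.27) mm
  m <- solid_cuboid_mask(10, 10, 4, spacing = c(1.37, 1.37, 3.27))
  expect_equal(bounding_box_dims(m), c(l = 13.7, b = 13.7, t = 13.08))
  empty <- list(grid = array(0L, c(3, 3, 3)), spacing = c(1, 1, 1))
  class(empty) <- "voxel_mask"
  expect_error(bounding_box_dims(empty), "empty ROI")
})

test_that("form factors match closed forms on exact box dimensions", {
  expect_equal(angelidakis_indices(c(1, 1, 1)),
               c(ael = 0, afl = 0, aco = 1))
  expect_equal(angelidakis_indices(c(4, 2, 1)),
               c(ael = 2 / 7, afl = 2 / 7, aco = 3 / 7))
  expect_equal(kong_indices(c(1, 1, 1)), c(kel = 0, kfl = 0))
  expect_equal(kong_indices(c(4, 2, 1)), c(kel = 0.5, kfl = 0.5))
  # scale invariance of the ratios
  expect_equal(kong_indices(c(2, 1, 0.5)), c(kel = 0.5, kfl = 0.5))
  expect_equal(max_projection_sphericity(c(1, 1, 1)), 1)
  expect_equal(max_projection_sphericity(c(4, 2, 1)), 0.5)
  expect_equal(max_projection_sphericity(c(2, 2, 1)), (1 / 4)^(1 / 3))

  expect_error(angelidakis_indices(c(1, 2, 3)), "l >= b >= t")
  expect_error(kong_indices(c(2, 1, 0)), "positive")
})

test_that("angelidakis decomposition sums to one and stays in range", {
  set.seed(41)
  dims <- random_box_dims(500)
  for (i in seq_len(nrow(dims))) {
    a <- angelidakis_indices(dims[i, ])
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_true(all(a >= 0 & a <= 1))
    expect_true(all(kong_indices(dims[i, ]) >= 0))
    mps <- max_projection_sphericity(dims[i, ])
    expect_true(mps > 0 && mps <= 1)
  }
})

test_that("voxel volume counts foreground voxels times voxel volume", {
  expect_equal(voxel_volume(single_voxel_mask()), 1)
  m <- solid_cuboid_mask(10, 10, 10, spacing = c(1.37, 1.37, 3.27))
  expect_equal(voxel_volume(m), 1000 * 1.37 * 1.37 * 3.27)
  ell <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(10, 5, 2.5),
                                   spacing = c(0.5, 0.5, 0.5)))
  expect_equal(voxel_volume(ell), 4 / 3 * pi * 10 * 5 * 2.5,
               tolerance = 0.02)
})

test_that("mesh surface area approaches closed forms and refines with resolution", {
  true_area <- 4 * pi * 100
  sph05 <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(10, 10, 10),
                                     spacing = rep(0.5, 3)))
  a05 <- surface_area(sph05)
  expect_lt(abs(a05 / true_area - 1), 0.03)
  sph025 <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(10, 10, 10),
                                      spacing = rep(0.25, 3)))
  a025 <- surface_area(sph025)
  expect_lt(abs(a025 / true_area - 1), 0.01)
  # voxel-face mode is exact for a single voxel cube
  expect_equal(surface_area(single_voxel_mask(), method = "voxel"), 6)
  # ... and for any axis-aligned cuboid
  expect_equal(surface_area(solid_cuboid_mask(4, 3, 2), method = "voxel"),
               2 * (4 * 3 + 4 * 2 + 3 * 2))
})

test_that("tiny masks fall back to the unsmoothed isosurface", {
  m <- single_voxel_mask()
  mesh <- surface_mesh(m)  # smoothing would wash out a single voxel
  expect_gt(nrow(mesh$vertices), 0)
  expect_gt(surface_area(mesh), 0)
})

test_that("maximum 3D diameter matches box diagonals and sphere diameters", {
  expect_equal(max_3d_diameter(solid_cuboid_mask(20, 10, 5)),
               sqrt(20^2 + 10^2 + 5^2))
  sp <- c(1.37, 1.37, 3.27)
  expect_equal(max_3d_diameter(single_voxel_mask(sp)), sqrt(sum(sp^2)))
  sph <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(10, 10, 10),
                                   spacing = rep(0.25, 3)))
  expect_lt(abs(max_3d_diameter(sph) / 20 - 1), 0.03)
})

test_that("sphericity and volume density follow their closed forms", {
  r <- 7
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1)
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6)
  expect_warning(s <- sphericity(4 / 3 * pi, 4 * pi * 0.99), "clipped")
  expect_equal(s, 1)
  expect_error(sphericity(0, 6), "positive")

  expect_equal(volume_density(1000, c(20, 10, 5)), 1)
  expect_equal(volume_density(pi / 6 * 8, c(2, 2, 2)), pi / 6)
  sph <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(10, 10, 10),
                                   spacing = rep(0.5, 3)))
  expect_lt(abs(suppressWarnings(extract_all(sph))[["sphericity"]] - 1), 0.05)
})

test_that("extract_all reproduces ellipsoid closed forms within voxelization error", {
  ell <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(10, 5, 2.5),
                                   spacing = rep(0.5, 3)))
  fv <- extract_all(ell)
  expect_named(fv, feature_names())
  expect_equal(fv[["ael"]], 2 / 7, tolerance = 0.03)
  expect_equal(fv[["afl"]], 2 / 7, tolerance = 0.03)
  expect_equal(fv[["aco"]], 3 / 7, tolerance = 0.03)
  expect_equal(fv[["kel"]], 0.5, tolerance = 0.03)
  expect_equal(fv[["kfl"]], 0.5, tolerance = 0.03)
  expect_equal(fv[["mps"]], 0.5, tolerance = 0.03)
  expect_equal(fv[["vdn"]], pi / 6, tolerance = 0.03)
  expect_equal(fv[["ael"]] + fv[["afl"]] + fv[["aco"]], 1, tolerance = 1e-9)
  expect_gte(fv[["max3ddiam"]], bounding_box_dims(ell)[["l"]])
  expect_true(all(fv[setdiff(feature_names(),
                             c("max3ddiam", "surfarea", "volume"))] >= 0))
})

test_that("features are scale invariant up to the expected powers of spacing", {
  ell <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(8, 5, 3),
                                   spacing = c(1, 1, 1)))
  f1 <- extract_all(ell)
  k <- 2.5
  scaled <- voxel_mask(ell$grid, spacing = ell$spacing * k)
  f2 <- extract_all(scaled)
  dimless <- setdiff(feature_names(), c("max3ddiam", "surfarea", "volume"))
  expect_equal(f2[dimless], f1[dimless], tolerance = 1e-10)
  expect_equal(f2[["max3ddiam"]], k * f1[["max3ddiam"]], tolerance = 1e-10)
  expect_equal(f2[["surfarea"]], k^2 * f1[["surfarea"]], tolerance = 1e-10)
  expect_equal(f2[["volume"]], k^3 * f1[["volume"]], tolerance = 1e-10)
})

test_that("features are invariant under grid axis permutation", {
  ell <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(8, 5, 3),
                                   spacing = c(1, 1, 1)))
  f1 <- extract_all(ell)
  perm <- c(3, 1, 2)
  permuted <- voxel_mask(aperm(ell$grid, perm), spacing = ell$spacing[perm])
  f2 <- extract_all(permuted)
  expect_equal(f2, f1, tolerance = 1e-10)
})

test_that("the axis-aligned box is deliberately not rotation invariant", {
  spec0 <- phantom_spec("ellipsoid", semi_axes = c(12, 4, 4),
                        spacing = c(0.5, 0.5, 0.5))
  spec45 <- phantom_spec("ellipsoid", semi_axes = c(12, 4, 4),
                         spacing = c(0.5, 0.5, 0.5), rotation = c(pi / 4, 0, 0))
  a0 <- angelidakis_indices(bounding_box_dims(make_phantom(spec0)))
  a45 <- angelidakis_indices(bounding_box_dims(make_phantom(spec45)))
  expect_gt(abs(a0[["ael"]] - a45[["ael"]]), 0.05)
})
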