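test_that("phantom generation is deterministic and has the stated tissues", {
  spec <- phantom_spec(grid_dims = c(32L, 32L, 32L), spacing = c(4, 4, 4),
                       seed = 0L)
  v1 <- make_phantom(spec)
  v2 <- make_phantom(spec)
  expect_identical(v1$voxels, v2$voxels)
  expect_gte(max(v1$voxels), 1000)              # bone present
  expect_equal(min(v1$voxels), -1000)           # air present
  expect_true(any(abs(v1$voxels - spec$brain_hu) < 100))  # soft tissue
  # interior air cavities: air voxels strictly inside the inner ellipsoid
  xyz <- noncopcbct:::voxel_coords(v1, v1$isocenter)
  inner <- (xyz[, 1] / spec$inner_semi_axes[1])^2 +
    (xyz[, 2] / spec$inner_semi_axes[2])^2 +
    (xyz[, 3] / spec$inner_semi_axes[3])^2 <= 0.9
  expect_true(any(v1$voxels[array(inner, dim(v1$voxels))] == -1000))
})

test_that("bone volume fraction matches the ellipsoid-shell formula", {
  spec <- phantom_spec(grid_dims = c(64L, 64L, 64L), spacing = c(2, 2, 2),
                       noise_sd = 0, seed = 1L)
  v <- make_phantom(spec)
  frac <- mean(v$voxels >= 1000)
  shell <- 4 / 3 * pi * (prod(spec$outer_semi_axes) -
                           prod(spec$inner_semi_axes))
  grid_vol <- prod(dim(v$voxels)) * prod(v$spacing)
  expect_equal(frac, shell / grid_vol, tolerance = 0.02)
})

test_that("infeasible phantom geometry is rejected", {
  expect_error(phantom_spec(outer_semi_axes = c(40, 40, 40),
                            inner_semi_axes = c(50, 36, 36)),
               "inside")
  expect_error(phantom_spec(bone_hu = 5000), "HU")
})

test_that("couch rotation is a rigid rotation about the vertical axis", {
  vol <- desk_phantom(24L, 6)
  expect_equal(rotate_couch(vol, 0)$voxels, vol$voxels)
  # +45 then -45 returns the original in the interior: exact on a smooth
  # field, high-correlation on the sharp-edged phantom
  blob <- cbct_volume(array(0, rep(24L, 3)), spacing = rep(6, 3))
  xyz <- noncopcbct:::voxel_coords(blob, blob$isocenter)
  blob$voxels <- array(1000 * exp(-rowSums(xyz^2) / (2 * 30^2)), rep(24L, 3))
  backb <- rotate_couch(rotate_couch(blob, 45), -45)
  core <- 7:18
  expect_lt(mean(abs(backb$voxels[core, core, core] -
                       blob$voxels[core, core, core])), 10)
  # on the discretized phantom the skull shell and sinuses are voxel-scale,
  # so double resampling can only preserve them approximately
  ph32 <- desk_phantom(32L, 4, seed = 2L, noise_sd = 0)
  back <- rotate_couch(rotate_couch(ph32, 45), -45)
  core32 <- 10:23
  expect_gt(stats::cor(as.vector(back$voxels[core32, core32, core32]),
                       as.vector(ph32$voxels[core32, core32, core32])), 0.8)
  # a landmark at +16 mm in x maps under +90 degrees about y to -16 mm in z
  lv <- cbct_volume(array(0, dim = c(33, 33, 33)), spacing = c(2, 2, 2))
  lv$voxels[25, 17, 17] <- 100
  rv <- rotate_couch(lv, 90)
  idx <- which(rv$voxels == max(rv$voxels), arr.ind = TRUE)
  expect_equal(as.integer(idx[1, ]), c(17L, 17L, 9L))
})

test_that("setup errors respect ranges, grids and uniform moments", {
  draws <- t(vapply(1:2000, function(i)
    as.numeric(sample_setup_error(seed = i)), numeric(6)))
  expect_true(all(abs(draws[, 1:3]) <= 10))
  expect_true(all(abs(draws[, 4:6]) <= 3))
  # 0.1 grid snapping: 10 * x is integer-valued
  expect_true(all(abs(draws * 10 - round(draws * 10)) < 1e-9))
  # uniform distribution moments: mean within 3 standard errors of 0
  se_t <- 10 / sqrt(3) / sqrt(nrow(draws))
  se_r <- 3 / sqrt(3) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws[, 1:3])) < 3 * se_t))
  expect_true(all(abs(colMeans(draws[, 4:6])) < 3 * se_r))
})

test_that("setup-error draws match the snapped-uniform distribution (KS)", {
  x <- vapply(1:3000, function(i) sample_setup_error(seed = 5000 + i)$tx,
              numeric(1))
  # exact pmf of a U(-10, 10) draw snapped to the 0.1 grid: interior grid
  # points collect a 0.1-wide interval, the two end points a half interval
  grid <- seq(-10, 10, by = 0.1)
  p <- c(0.05, rep(0.1, length(grid) - 2), 0.05) / 20
  cdf <- cumsum(p)
  ecdf_at <- vapply(grid, function(g) mean(x <= g + 1e-9), numeric(1))
  D <- max(abs(ecdf_at - cdf))
  # Kolmogorov critical value at alpha = 0.01 (conservative for discrete)
  expect_lt(D, 1.63 / sqrt(length(x)))
})

test_that("rigid resampling honors identity, inversion and translation", {
  vol <- desk_phantom(24L, 6)
  expect_identical(apply_rigid(vol, rigid_transform()), vol)
  tr <- rigid_transform(3, -2, 1, 1.5, -2, 0.5)
  blob <- cbct_volume(array(0, rep(24L, 3)), spacing = rep(6, 3))
  bx <- noncopcbct:::voxel_coords(blob, blob$isocenter)
  blob$voxels <- array(1000 * exp(-rowSums(bx^2) / (2 * 30^2)), rep(24L, 3))
  back <- apply_rigid(apply_rigid(blob, tr, fill = 0), invert_rigid(tr),
                      fill = 0)
  core <- 7:18
  expect_lt(mean(abs(back$voxels[core, core, core] -
                       blob$voxels[core, core, core])), 10)
  # pure +5 mm shift in z moves the center of mass by +5 mm within half a
  # voxel (density above air; a binary mask of the one-voxel-thin skull
  # shell is not centroid-stable under sub-voxel resampling)
  ph <- desk_phantom(32L, 4, seed = 6L)
  shifted <- apply_rigid(ph, rigid_transform(tz = 5))
  xyz <- noncopcbct:::voxel_coords(ph, c(0, 0, 0))
  m0 <- as.numeric(ph$voxels + 1000)
  m1 <- as.numeric(shifted$voxels + 1000)
  delta <- colSums(xyz * m1) / sum(m1) - colSums(xyz * m0) / sum(m0)
  expect_lt(abs(delta[3] - 5), 2)       # half of the 4 mm voxel
  expect_lt(max(abs(delta[1:2])), 2)
})

test_that("rigid transforms compose, invert and map points analytically", {
  a <- rigid_transform(1, 2, -3, 5, -4, 10)
  b <- rigid_transform(-2, 0.5, 1, -3, 7, 2)
  p <- matrix(c(10, -20, 5, 0, 0, 0, 3, 4, -7), ncol = 3, byrow = TRUE)
  expect_equal(transform_points(compose_rigid(a, b), p),
               transform_points(a, transform_points(b, p)), tolerance = 1e-10)
  ident <- compose_rigid(a, invert_rigid(a))
  expect_lt(max(abs(as.numeric(ident))), 1e-10)
  # pure z rotation of a point on the x axis
  rz <- rigid_transform(rz = 90)
  expect_equal(as.numeric(transform_points(rz, c(1, 0, 0))),
               c(0, 1, 0), tolerance = 1e-12)
})

test_that("dataset arithmetic and sample invariants hold", {
  plan <- plan_dataset(40, c(45, -45, 90, -90), 5, seed = 1L)
  expect_equal(nrow(plan), 800L)
  plan2 <- plan_dataset(2, c(45, -45, 90, -90), 3, seed = 1L)
  expect_equal(nrow(plan2), 24L)
  expect_true(all(abs(plan$tx) <= 10 & abs(plan$rx) <= 3))
  expect_error(plan_dataset(2, 45, 0), "repeats")

  ds <- tiny_dataset(n_phantoms = 1L, couch = 90, repeats = 2L)
  expect_length(ds, 2L)
  s <- ds[[1]]
  # ground truth is the couch-rotated, error-moved prior by construction
  rebuilt <- apply_rigid(rotate_couch(s$coplanar_cbct, s$couch_angle),
                         s$setup_error)
  expect_identical(rebuilt$voxels, s$ground_truth$voxels)
  # re-casting the stored projections from the ground truth is bit-identical
  recast <- simulate_scan(s$ground_truth, s$projections$geometry,
                          couch_arc(90), couch_angle = 90)
  expect_identical(recast$images, s$projections$images)
})

test_that("dataset plans are reproducible and seeds are splittable", {
  p1 <- plan_dataset(3, c(45, 90), 2, seed = 7L)
  p2 <- plan_dataset(3, c(45, 90), 2, seed = 7L)
  expect_identical(p1, p2)
  expect_false(any(duplicated(p1$seed)))
  expect_true(all(p1$seed < 2^31))
})
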