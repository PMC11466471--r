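test_that("difference image is the signed voxelwise difference", {
  a <- desk_phantom(16L, 8, seed = 1L)
  b <- a; b$voxels <- a$voxels - 50
  expect_true(all(difference_image(a, a)$voxels == 0))
  expect_true(all(difference_image(a, b)$voxels == 50))
  expect_equal(difference_image(a, b)$voxels,
               -difference_image(b, a)$voxels)
  bad <- cbct_volume(array(0, c(4, 4, 4)), spacing = c(8, 8, 8))
  expect_error(difference_image(a, bad), "mismatch")
})

test_that("RMSE matches brute force and behaves like a metric", {
  a <- desk_phantom(16L, 8, seed = 1L)
  expect_equal(rmse(a, a), 0)
  b <- a; b$voxels <- a$voxels + 100
  expect_equal(rmse(a, b), 100)
  set.seed(6)
  x <- a; x$voxels <- array(rnorm(16^3, sd = 50), rep(16, 3))
  y <- a; y$voxels <- array(rnorm(16^3, sd = 50), rep(16, 3))
  z <- a; z$voxels <- array(rnorm(16^3, sd = 50), rep(16, 3))
  brute <- sqrt(sum((x$voxels - y$voxels)^2) / length(x$voxels))
  expect_equal(rmse(x, y), brute, tolerance = 1e-12)
  expect_equal(rmse(x, y), rmse(y, x))
  expect_lte(rmse(x, z), rmse(x, y) + rmse(y, z) + 1e-12)
  mask <- x$voxels > 0
  expect_equal(rmse(x, y, mask),
               sqrt(mean((x$voxels[mask] - y$voxels[mask])^2)))
  expect_error(rmse(x, y, mask & !mask), "mask")
})

test_that("sphere grids have the constructed counts at exact radius", {
  s <- sphere_points(30, 5)
  expect_equal(nrow(s$points), 35 * 72 + 2)
  expect_true(all(abs(sqrt(rowSums(s$points^2)) - 30) < 1e-9))
  expect_equal(nrow(sphere_points(30, 90)$points), 1 * 4 + 2)  # octahedral
  expect_error(sphere_points(30, 0), "sep")
})

test_that("sphere-integrated error matches closed forms and the chord oracle", {
  s <- sphere_points(30, 5)
  expect_equal(overall_registration_error(rigid_transform(), s), 0)
  expect_equal(overall_registration_error(rigid_transform(3, 4, 0), s), 5.0,
               tolerance = 1e-12)
  expect_equal(overall_registration_error(rigid_transform(3, 4, 0),
                                          sphere_points(30, 15)), 5.0,
               tolerance = 1e-12)  # any grid, pure translation
  # rotation by a about z displaces each point by 2 r sin(a/2) sin(theta)
  for (a in c(0.5, 2, 3)) {
    eps <- overall_registration_error(rigid_transform(rz = a), s)
    theta <- acos(pmin(1, pmax(-1, s$points[, 3] / 30)))
    oracle <- mean(2 * 30 * sin(a * pi / 360) * sin(theta))
    expect_equal(eps, oracle, tolerance = 1e-9)
  }
})

test_that("epsilon is stable under grid rotation and subadditive", {
  s <- sphere_points(30, 5)
  t1 <- rigid_transform(rx = 1.5, ty = 2)
  t2 <- rigid_transform(rz = -2, tx = -1)
  # azimuthal re-orientation of the grid: rotate all points about z
  rotg <- s
  rotg$points <- transform_points(rigid_transform(rz = 33), s$points)
  e1 <- overall_registration_error(t1, s)
  expect_equal(overall_registration_error(t1, rotg), e1, tolerance = 0.01)
  e12 <- overall_registration_error(compose_rigid(t1, t2), s)
  expect_lte(e12, e1 + overall_registration_error(t2, s) + 1e-9)
})

test_that("rigid registration recovers identity and injected motions", {
  ph <- desk_phantom(32L, 4, seed = 2L)
  est0 <- rigid_register(ph, ph)
  expect_true(all(abs(as.numeric(est0)) < 0.05))
  tr <- rigid_transform(3, -2, 1)
  est <- rigid_register(apply_rigid(ph, tr), ph)
  expect_true(all(abs(as.numeric(est)[1:3] - c(-3, 2, -1)) < 0.3))
  trz <- rigid_transform(rz = 2)
  estz <- rigid_register(apply_rigid(ph, trz), ph)
  expect_lt(abs(as.numeric(estz)[6] + 2), 0.3)
})

test_that("bone SSIM is 1 for identity, drops under erosion, matches brute force", {
  ph <- desk_phantom(24L, 5, seed = 3L)
  expect_equal(bone_ssim(ph, ph), 1.0)
  er <- ph
  bone_idx <- which(er$voxels >= 1000)
  er$voxels[bone_idx[seq_len(80)]] <- 500
  expect_lt(bone_ssim(ph, er), 1.0)
  air <- cbct_volume(array(-1000, rep(8L, 3)), spacing = rep(5, 3))
  expect_error(bone_ssim(air, air), "threshold")
  # uniform-window value against a direct sliding-window reference
  set.seed(8)
  d <- rep(10L, 3)
  a <- cbct_volume(array(900 + 300 * runif(prod(d)), d), spacing = rep(2, 3))
  b <- cbct_volume(array(900 + 300 * runif(prod(d)), d), spacing = rep(2, 3))
  w <- 3L; half <- 1L
  th <- function(v) { v[v < 1000] <- 0; v }
  av <- th(a$voxels); bv <- th(b$voxels)
  pad <- function(v) {
    idx <- function(n) pmin(pmax(0:(n + 1), 1), n)
    v[idx(d[1]), idx(d[2]), idx(d[3])]
  }
  ap <- pad(av); bp <- pad(bv)
  C1 <- (0.01 * 3000)^2; C2 <- (0.03 * 3000)^2
  ref <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    wa <- ap[x:(x + 2), y:(y + 2), z:(z + 2)]
    wb <- bp[x:(x + 2), y:(y + 2), z:(z + 2)]
    ma <- mean(wa); mb <- mean(wb)
    va <- mean(wa^2) - ma^2; vb <- mean(wb^2) - mb^2
    cab <- mean(wa * wb) - ma * mb
    ref[x, y, z] <- (2 * ma * mb + C1) * (2 * cab + C2) /
      ((ma^2 + mb^2 + C1) * (va + vb + C2))
  }
  got <- bone_ssim(a, b, window = "uniform", window_size = w)
  expect_equal(got, mean(ref), tolerance = 1e-6)
})

test_that("evaluate_sample aggregates metrics and round-trips JSON", {
  ph <- desk_phantom(32L, 4, seed = 4L)
  rep0 <- evaluate_sample(ph, ph)
  expect_equal(rep0$rmse, 0)
  expect_lt(rep0$epsilon, 0.05)
  tr <- rigid_transform(1.5, -1, 0.5, 0.8, -0.5, 1.2)
  moved <- apply_rigid(ph, tr)
  repm <- evaluate_sample(ph, moved)
  oracle <- overall_registration_error(invert_rigid(tr))
  expect_lt(abs(repm$epsilon - oracle) / oracle, 0.2)
  tmp <- tempfile(fileext = ".json")
  write_report(repm, tmp)
  back <- read_report(tmp)
  expect_equal(back$rmse, repm$rmse, tolerance = 1e-12)
  expect_equal(back$epsilon, repm$epsilon, tolerance = 1e-12)
  expect_equal(back$transform, repm$transform, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("group comparison wrapper runs a rank-sum test", {
  set.seed(10)
  out <- compare_groups(rnorm(10, 50, 5), rnorm(10, 70, 5))
  expect_s3_class(out, "htest")
  expect_lt(out$p.value, 0.05)
})
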