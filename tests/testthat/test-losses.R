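test_that("soft bone mask is 0.5 at threshold, saturates and is monotone", {
  cfg <- loss_config()
  expect_equal(as.numeric(bone_soft_mask(array(1000, c(1, 1, 1)), cfg)), 0.5)
  expect_gt(as.numeric(bone_soft_mask(array(2000, c(1, 1, 1)), cfg)),
            1 - 1e-6)
  expect_lt(as.numeric(bone_soft_mask(array(0, c(1, 1, 1)), cfg)), 1e-6)
  hu <- array(seq(-1000, 2000, length.out = 64), c(4, 4, 4))
  m <- bone_soft_mask(hu, loss_config(scale = 20))
  expect_true(all(diff(as.vector(m)) >= 0))
  expect_true(all(m > 0 & m < 1))
  # raw-HU mode keeps the literal threshold behavior
  raw <- loss_config(scale = 0.01, normalize = FALSE)
  expect_equal(as.numeric(bone_soft_mask(array(1000, c(1, 1, 1)), raw)), 0.5)
})

test_that("soft bone mask gradient matches central finite differences", {
  cfg <- loss_config(scale = 50)
  for (x0 in c(950, 1000, 1080)) {
    h <- 1e-3
    fd <- (as.numeric(bone_soft_mask(array(x0 + h, c(1, 1, 1)), cfg)) -
             as.numeric(bone_soft_mask(array(x0 - h, c(1, 1, 1)), cfg))) /
      (2 * h)
    an <- as.numeric(bone_soft_mask_grad(array(x0, c(1, 1, 1)), cfg))
    expect_equal(fd, an, tolerance = 1e-4)
  }
})

test_that("Sobel edges: flat fields, step gain by direct convolution, symmetry", {
  flat <- array(7, c(5, 5, 5))
  expect_lt(max(sobel_edges(flat)), 1e-3)  # only the eps stabilizer
  # axis-aligned step of height h: compare the interior response against a
  # brute-force convolution with the separable kernels on the padded array
  h <- 2
  g <- array(0, c(5, 5, 5)); g[4:5, , ] <- h
  dvec <- c(-1, 0, 1); svec <- c(1, 2, 1)
  kx <- outer(dvec, svec) %o% svec
  pad <- function(v) {
    idx <- function(n) pmin(pmax(0:(n + 1), 1), n)
    v[idx(dim(v)[1]), idx(dim(v)[2]), idx(dim(v)[3])]
  }
  gp <- pad(g)
  brute <- array(0, c(5, 5, 5))
  for (x in 1:5) for (y in 1:5) for (z in 1:5)
    brute[x, y, z] <- sum(gp[x:(x + 2), y:(y + 2), z:(z + 2)] * kx)
  e <- sobel_edges(g)
  expect_equal(e, sqrt(brute^2 + 1e-8), tolerance = 1e-10)
  expect_equal(e[3, 3, 3], h * 16, tolerance = 1e-3)  # kernel step gain
  # rotating the input by 90 degrees permutes the edge map identically
  g2 <- aperm(g, c(3, 1, 2))
  expect_equal(sobel_edges(g2), aperm(e, c(3, 1, 2)), tolerance = 1e-12)
})

test_that("radial central moments: point mass, translation invariance, ball", {
  d <- c(9, 9, 9)
  w <- array(0, d); w[3, 4, 5] <- 2.5
  expect_equal(central_moments(w, c(1, 1, 1), 4), rep(0, 4))
  # translated copy has identical moments (exact on-grid shift)
  set.seed(1)
  w2 <- array(0, d); w2[2:4, 2:4, 2:4] <- runif(27)
  w3 <- array(0, d); w3[6:8, 5:7, 4:6] <- w2[2:4, 2:4, 2:4]
  expect_equal(central_moments(w2, c(2, 2, 2), 4),
               central_moments(w3, c(2, 2, 2), 4), tolerance = 1e-12)
  expect_error(central_moments(array(0, d), c(1, 1, 1), 4), "mass")
  # uniform ball: m_j = 3 R^j / (j + 3)
  dim3 <- rep(96L, 3)
  vol <- cbct_volume(array(0, dim3), spacing = c(1, 1, 1))
  xyz <- noncopcbct:::voxel_coords(vol, vol$isocenter)
  R <- 30
  wball <- array(as.numeric(sqrt(rowSums(xyz^2)) <= R), dim3)
  m <- central_moments(wball, c(1, 1, 1), 4)
  expect_equal(m, 3 * R^(1:4) / ((1:4) + 3), tolerance = 0.02)
})

test_that("radial moment gradients match central finite differences", {
  set.seed(3)
  d <- c(7, 7, 7)
  w <- array(runif(prod(d)) + 0.1, d)
  cm <- noncopcbct:::central_moments_full(w, c(1, 1, 1), 4)
  gr <- noncopcbct:::central_moments_grad(cm)
  h <- 1e-6
  for (i in c(17L, 123L, 311L)) {
    wp <- w; wp[i] <- w[i] + h
    wm <- w; wm[i] <- w[i] - h
    for (j in 1:4) {
      fd <- (central_moments(wp, c(1, 1, 1), 4)[j] -
               central_moments(wm, c(1, 1, 1), 4)[j]) / (2 * h)
      expect_equal(gr[[j]][i], fd, tolerance = 1e-3)
    }
  }
})

test_that("rigid-bone loss is invariant to rigid motion, sensitive to shape", {
  ph <- desk_phantom(32L, 4, seed = 1L)
  cfg <- loss_config()
  expect_equal(rigid_bone_loss(ph, ph, cfg), 0)
  m_ref <- central_moments(sobel_edges(bone_soft_mask(ph, cfg)),
                           ph$spacing / noncopcbct:::half_diagonal(ph), 4)
  tau <- 0.1 * sqrt(sum(m_ref^2))   # resampling tolerance
  for (i in 1:3) {
    tr <- sample_setup_error(seed = 40 + i)
    expect_lt(rigid_bone_loss(ph, apply_rigid(ph, tr), cfg), tau)
  }
  spec <- phantom_spec(grid_dims = rep(32L, 3), spacing = rep(4, 3),
                       noise_sd = 20, seed = 1L)
  dil <- phantom_spec(grid_dims = rep(32L, 3), spacing = rep(4, 3),
                      noise_sd = 20, seed = 1L,
                      outer_semi_axes = spec$outer_semi_axes * 1.1,
                      inner_semi_axes = spec$inner_semi_axes * 1.1)
  expect_gt(rigid_bone_loss(ph, make_phantom(dil), cfg), tau)
  # missing bone raises an informative error in the moments
  air <- cbct_volume(array(-1000, dim = rep(8L, 3)), spacing = rep(4, 3))
  expect_error(central_moments(array(0, rep(8L, 3))), "mass")
})

test_that("rigid-bone loss gradient matches central finite differences", {
  set.seed(3)
  cfg <- loss_config(scale = 2000)
  d <- c(8, 8, 8)
  ref <- cbct_volume(array(800 + 400 * runif(prod(d)), d),
                     spacing = c(4, 4, 4))
  rec <- cbct_volume(array(800 + 400 * runif(prod(d)), d),
                     spacing = c(4, 4, 4))
  g <- rigid_bone_loss_grad(ref, rec, cfg)
  h <- 1e-3
  idx <- order(abs(g), decreasing = TRUE)[c(1, 25, 100)]
  for (i in idx) {
    vp <- rec; vp$voxels[i] <- vp$voxels[i] + h
    vm <- rec; vm$voxels[i] <- vm$voxels[i] - h
    fd <- (rigid_bone_loss(ref, vp, cfg) - rigid_bone_loss(ref, vm, cfg)) /
      (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-3)
  }
})

test_that("L1 loss matches brute force and validates shapes", {
  a <- cbct_volume(array(1:27, c(3, 3, 3)), spacing = c(1, 1, 1))
  expect_equal(l1_loss(a, a), 0)
  b <- a; b$voxels <- a$voxels + 10
  expect_equal(l1_loss(a, b), 10)
  set.seed(2)
  x <- array(rnorm(64), c(4, 4, 4)); y <- array(rnorm(64), c(4, 4, 4))
  expect_equal(l1_loss(x, y), sum(abs(x - y)) / 64)
  expect_error(l1_loss(x, array(0, c(4, 4, 2))), "mismatch")
})

test_that("adversarial terms reproduce closed forms and clamp extremes", {
  g <- gan_losses(0.5, 0.5)
  expect_equal(g$discriminator, 2 * log(2), tolerance = 1e-12)
  expect_equal(g$generator, log(2), tolerance = 1e-12)
  expect_lt(gan_losses(0.9, 1 - 1e-12)$generator, 1e-6)   # d_fake -> 1
  expect_true(is.finite(gan_losses(0, 1)$discriminator))  # clamped
  # batch form equals the scalar-by-scalar average
  set.seed(4)
  dr <- runif(10, 0.1, 0.9); df <- runif(10, 0.1, 0.9)
  brute_d <- mean(-log(dr)) + mean(-log(1 - df))
  brute_g <- mean(-log(df))
  gb <- gan_losses(dr, df)
  expect_equal(gb$discriminator, brute_d, tolerance = 1e-12)
  expect_equal(gb$generator, brute_g, tolerance = 1e-12)
  # saturating variant is the literal minimax term
  expect_equal(gan_losses(dr, df, saturating = TRUE)$generator,
               mean(log(1 - df)), tolerance = 1e-12)
})

test_that("joint objective weights components linearly", {
  cfg <- loss_config()
  expect_equal(joint_loss(1.7, 0, 0, cfg), 1.7)
  expect_equal(joint_loss(0, 1, 1, cfg), 100.1)
  base <- joint_loss(0.3, 0.2, 0.5, cfg)
  dbl <- joint_loss(0.3, 0.2, 0.5, loss_config(lambda1 = 200))
  expect_equal(dbl - base, 100 * 0.2, tolerance = 1e-12)
  expect_gt(joint_loss(0.3, 0.25, 0.5, cfg), base)  # monotone in each term
})
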