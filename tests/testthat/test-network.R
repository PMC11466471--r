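test_that("generator maps desk-scale inputs to the volume grid", {
  set.seed(1)
  gen <- build_generator(generator_config(base_channels = 2L,
                                          latent_width = 8L, seed = 3L))
  out <- generator_forward(gen, array(rnorm(16^3), rep(16, 3)),
                           array(rnorm(16^3), rep(16, 3)))
  expect_equal(dim(out), c(16L, 16L, 16L))
  expect_true(all(is.finite(out)))
  expect_error(generator_forward(gen, array(0, rep(8, 3)),
                                 array(0, rep(16, 3))), "shape")
})

test_that("a 64-cube generator with a 32x48x48 projection stack restores 64^3", {
  set.seed(2)
  cfg <- generator_config(volume_shape = rep(64L, 3),
                          projection_shape = c(32L, 48L, 48L),
                          base_channels = 1L, latent_width = 8L, seed = 1L)
  gen <- build_generator(cfg)
  out <- generator_forward(gen, array(rnorm(64^3), rep(64, 3)),
                           array(rnorm(32 * 48 * 48), c(32, 48, 48)))
  expect_equal(dim(out), c(64L, 64L, 64L))
  expect_true(all(is.finite(out)))
})

test_that("both encoder branches are live", {
  set.seed(3)
  gen <- build_generator(generator_config(base_channels = 2L,
                                          latent_width = 8L, seed = 5L))
  v <- array(rnorm(16^3), rep(16, 3))
  p1 <- array(rnorm(16^3), rep(16, 3))
  p2 <- array(0, rep(16, 3))
  o1 <- generator_forward(gen, v, p1)
  o2 <- generator_forward(gen, v, p2)
  expect_gt(max(abs(o1 - o2)), 0)
  o3 <- generator_forward(gen, v * 0, p1)
  expect_gt(max(abs(o1 - o3)), 0)
})

test_that("parameter count matches the layer-algebra closed form", {
  bc <- 4L; lw <- 16L
  cfg <- generator_config(base_channels = bc, latent_width = lw, seed = 0L)
  gen <- build_generator(cfg)
  conv_p <- function(ci, co) 27 * ci * co + co
  block_p <- function(ci, co) conv_p(ci, co) + 2 * co + 1 +
    conv_p(co, co) + 2 * co + 1
  ch <- bc * 2L^(0:3)
  enc <- block_p(1, ch[1]) + block_p(ch[1], ch[2]) +
    block_p(ch[2], ch[3]) + block_p(ch[3], ch[4])
  bneck <- ch[4] * 1L            # 16^3 -> 1^3 after four blocks
  enc <- enc + (bneck * lw + lw) + 1 + (lw * lw + lw)
  dch <- rev(ch)
  dec <- (2 * lw) * bneck + bneck + 1    # fusion FC + pReLU
  dblock <- function(ci, co) (ci * 8 * co + co) + conv_p(co, co) + 2 * co +
    1 + conv_p(co, co) + 2 * co + 1
  dec <- dec + dblock(dch[1], dch[2]) + dblock(dch[2], dch[3]) +
    dblock(dch[3], dch[4]) + dblock(dch[4], bc) + conv_p(bc, 1)
  expect_equal(count_parameters(gen), 2 * enc + dec)
})

test_that("encoder blocks reduce and decoder blocks restore resolution", {
  gen <- build_generator(generator_config(base_channels = 2L,
                                          latent_width = 8L, seed = 2L))
  fw <- generator_forward(gen, array(rnorm(16^3), rep(16, 3)),
                          array(rnorm(16^3), rep(16, 3)), with_cache = TRUE)
  # bottleneck after four halvings of 16 is 1^3
  pooled_dims <- fw$f1$caches[[28]]$in_dim   # input of the last maxpool
  expect_equal(pooled_dims[1:3], c(2L, 2L, 2L))
  expect_equal(dim(fw$out), c(16L, 16L, 16L))
  expect_error(generator_config(volume_shape = c(24L, 24L, 24L)),
               "divisible")
})

test_that("BN and pReLU follow every stated convolution", {
  gen <- build_generator(generator_config(base_channels = 2L,
                                          latent_width = 8L, seed = 2L))
  summ <- architecture_summary(gen)
  enc <- summ[summ$part == "vol_branch", ]
  conv_rows <- which(enc$type == "conv3")
  for (r in conv_rows) {
    expect_equal(enc$type[r + 1], "bn")
    expect_equal(enc$type[r + 2], "prelu")
  }
  disc <- build_discriminator(discriminator_config(seed = 1L))
  ds <- architecture_summary(disc)
  expect_equal(sum(ds$type == "conv3"), 5L)   # five conv stages
  dconv <- which(ds$type == "conv3")
  expect_true(all(ds$type[dconv + 1] == "bn"))
  expect_true(all(ds$type[dconv + 2] == "prelu"))
  expect_equal(ds$type[nrow(ds)], "sigmoid")
})

test_that("pReLU slope is learnable (nonzero gradient)", {
  set.seed(9)
  x <- array(rnorm(27), c(3, 3, 3, 1))
  layer <- noncopcbct:::layer_prelu()
  fw <- noncopcbct:::layer_forward(layer, x)
  bw <- noncopcbct:::layer_backward(layer, fw$cache,
                                    array(1, dim = dim(x)))
  expect_true(bw$dparams$a != 0)
})

test_that("discriminator outputs probabilities, deterministically in eval", {
  set.seed(4)
  disc <- build_discriminator(discriminator_config(seed = 7L))
  p <- replicate(3, discriminator_forward(disc, array(rnorm(512), rep(8, 3))))
  expect_true(all(p > 0 & p < 1))
  x <- array(rnorm(512), rep(8, 3))
  expect_identical(discriminator_forward(disc, x),
                   discriminator_forward(disc, x))
  expect_error(discriminator_forward(disc, array(0, rep(4, 3))), "patch")
})

test_that("backpropagated gradients match finite differences across layers", {
  set.seed(5)
  gen <- build_generator(generator_config(base_channels = 2L,
                                          latent_width = 8L, seed = 3L))
  v <- array(rnorm(16^3), rep(16, 3))
  pr <- array(rnorm(16^3), rep(16, 3))
  w <- array(rnorm(16^3), rep(16, 3))
  fw <- generator_forward(gen, v, pr, with_cache = TRUE)
  gr <- noncopcbct:::generator_backward(gen, fw, w)
  L <- function(g) sum(generator_forward(g, v, pr) * w)
  h <- 1e-5
  cases <- list(c("vol_branch", 1L), c("proj_branch", 8L), c("decoder", 4L),
                c("decoder", 12L), c("vol_branch", 30L))
  for (cs in cases) {
    part <- cs[1]; li <- as.integer(cs[2])
    pname <- names(gen[[part]][[li]]$params)[1]
    idx <- 1L
    g2 <- gen; g2[[part]][[li]]$params[[pname]][idx] <-
      g2[[part]][[li]]$params[[pname]][idx] + h
    g3 <- gen; g3[[part]][[li]]$params[[pname]][idx] <-
      g3[[part]][[li]]$params[[pname]][idx] - h
    fd <- (L(g2) - L(g3)) / (2 * h)
    expect_equal(gr[[part]][[li]][[pname]][idx], fd, tolerance = 1e-3)
  }
  # discriminator input gradient (the path the adversarial term uses)
  disc <- build_discriminator(discriminator_config(
    channels = c(3L, 4L, 4L, 5L, 5L), seed = 2L))
  x <- array(rnorm(512), rep(8, 3))
  dfw <- discriminator_forward(disc, x, with_cache = TRUE)
  dbw <- noncopcbct:::discriminator_backward(disc, dfw$fw, 1)
  for (i in c(5L, 300L)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    fd <- (discriminator_forward(disc, xp) -
             discriminator_forward(disc, xm)) / (2 * h)
    expect_equal(dbw$dx[i], fd, tolerance = 1e-3)
  }
})
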