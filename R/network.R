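#' Generator configuration
#'
#' The generator is a dual-branch encoder plus decoder: one encoder ingests
#' the coplanar prior volume, the other the resampled limited-angle
#' projection stack; their fully connected outputs are concatenated and a
#' decoder maps the fused code back to the full volume grid. Each encoder has
#' four convolutional blocks (two 3x3x3 conv+BN+pReLU, then 2x2x2
#' max-pooling) followed by two fully connected layers; the decoder has one
#' fully connected layer and four deconvolutional blocks (2x2x2 stride-2
#' transposed convolution, then two 3x3x3 conv+BN+pReLU), closed by a linear
#' 3x3x3 convolution to one channel. All spatial dims must therefore be
#' divisible by 2^4.
#'
#' With `conv_stride = 2` the in-block convolutions are additionally strided
#' (an aggressive-reduction variant; requires correspondingly larger grids);
#' the default keeps stride-1 convolutions so each block halves resolution
#' exactly once.
#'
#' @param volume_shape voxel dims of the prior-volume branch input.
#' @param projection_shape (angles, rows, cols) grid of the projection branch
#'   (see [resample_projections()]).
#' @param base_channels channels of the first block (doubled each block).
#' @param latent_width width of each branch's final fully connected output.
#' @param conv_stride stride of in-block convolutions (1 or 2).
#' @param seed weight-initialization seed.
#' @return A `generator_config` object.
#' @export
generator_config <- function(volume_shape = c(16L, 16L, 16L),
                             projection_shape = c(16L, 16L, 16L),
                             base_channels = 8L, latent_width = 32L,
                             conv_stride = 1L, seed = 0L) {
  volume_shape <- as.integer(volume_shape)
  projection_shape <- as.integer(projection_shape)
  red <- if (conv_stride == 2L) 2L^3L else 2L  # per-block reduction factor
  total <- red^4L
  if (any(volume_shape %% total != 0) || any(projection_shape %% total != 0))
    stop("spatial shapes must be divisible by ", total,
         " (four encoder blocks at this stride)")
  if (base_channels < 1) stop("`base_channels` must be >= 1")
  structure(list(volume_shape = volume_shape,
                 projection_shape = projection_shape,
                 base_channels = as.integer(base_channels),
                 latent_width = as.integer(latent_width),
                 conv_stride = as.integer(conv_stride),
                 n_blocks = 4L, seed = as.integer(seed)),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Patch-based discriminator: five 3x3x3 conv+BN+pReLU stages followed by a
#' fully connected layer with sigmoid output; a volume is scored as the mean
#' over randomly sampled patches.
#'
#' @param patch_size cubic patch edge in voxels.
#' @param patches_per_volume patches sampled per volume score.
#' @param channels channel schedule of the 5 conv stages.
#' @param seed weight-initialization seed.
#' @return A `discriminator_config` object.
#' @export
discriminator_config <- function(patch_size = 8L, patches_per_volume = 8L,
                                 channels = c(8L, 16L, 16L, 32L, 32L),
                                 seed = 1L) {
  if (length(channels) != 5L) stop("exactly 5 conv stages required")
  structure(list(patch_size = as.integer(patch_size),
                 patches_per_volume = as.integer(patches_per_volume),
                 channels = as.integer(channels), seed = as.integer(seed)),
            class = "discriminator_config")
}

encoder_block <- function(rng, in_ch, out_ch, stride) {
  list(layer_conv3(rng, in_ch, out_ch, stride = stride),
       layer_bn(out_ch), layer_prelu(),
       layer_conv3(rng, out_ch, out_ch, stride = stride),
       layer_bn(out_ch), layer_prelu(),
       layer_maxpool())
}

decoder_block <- function(rng, in_ch, out_ch) {
  list(layer_deconv2(rng, in_ch, out_ch),
       layer_conv3(rng, out_ch, out_ch),
       layer_bn(out_ch), layer_prelu(),
       layer_conv3(rng, out_ch, out_ch),
       layer_bn(out_ch), layer_prelu())
}

encoder_branch <- function(rng, cfg, in_shape) {
  ch <- cfg$base_channels * 2L^(0:(cfg$n_blocks - 1L))
  layers <- list()
  in_ch <- 1L
  sp <- in_shape
  red <- if (cfg$conv_stride == 2L) 8L else 2L
  for (b in seq_len(cfg$n_blocks)) {
    layers <- c(layers, encoder_block(rng, in_ch, ch[b], cfg$conv_stride))
    in_ch <- ch[b]
    sp <- sp %/% red
  }
  n_bottleneck <- prod(sp) * in_ch
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(rng, n_bottleneck, cfg$latent_width), layer_prelu(),
    layer_dense(rng, cfg$latent_width, cfg$latent_width)))
  list(layers = layers, bottleneck_sp = sp, bottleneck_ch = in_ch)
}

#' Build the generator
#'
#' @param cfg a [generator_config()].
#' @return A `generator` object (layer lists for the two encoder branches and
#'   the decoder, plus the config).
#' @export
build_generator <- function(cfg = generator_config()) {
  rng <- nn_rng(cfg$seed)
  volb <- encoder_branch(rng, cfg, cfg$volume_shape)
  projb <- encoder_branch(rng, cfg, cfg$projection_shape)
  ch <- rev(cfg$base_channels * 2L^(0:(cfg$n_blocks - 1L)))
  sp <- volb$bottleneck_sp
  dec <- list(
    layer_dense(rng, 2L * cfg$latent_width, prod(sp) * ch[1]),
    layer_prelu(),
    layer_reshape(c(sp, ch[1])))
  in_ch <- ch[1]
  out_seq <- c(ch[-1], cfg$base_channels)
  for (b in seq_len(cfg$n_blocks)) {
    dec <- c(dec, decoder_block(rng, in_ch, out_seq[b]))
    in_ch <- out_seq[b]
  }
  dec <- c(dec, list(layer_conv3(rng, in_ch, 1L)))  # linear output head
  structure(list(cfg = cfg, vol_branch = volb$layers,
                 proj_branch = projb$layers, decoder = dec),
            class = "generator")
}

#' Build the discriminator
#'
#' @param cfg a [discriminator_config()].
#' @return A `discriminator` object.
#' @export
build_discriminator <- function(cfg = discriminator_config()) {
  rng <- nn_rng(cfg$seed)
  layers <- list()
  in_ch <- 1L
  for (s in seq_len(5L)) {
    layers <- c(layers, list(layer_conv3(rng, in_ch, cfg$channels[s]),
                             layer_bn(cfg$channels[s]), layer_prelu()))
    in_ch <- cfg$channels[s]
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(rng, cfg$patch_size^3 * in_ch, 1L),
    layer_sigmoid()))
  structure(list(cfg = cfg, layers = layers), class = "discriminator")
}

#' Generator forward pass
#'
#' @param gen a [build_generator()] model.
#' @param volume_input normalized prior volume, array matching
#'   `cfg$volume_shape` (a trailing channel dim of 1 is added).
#' @param proj_input normalized projection grid matching
#'   `cfg$projection_shape`.
#' @param with_cache keep layer caches for backpropagation.
#' @return Array of `cfg$volume_shape` (the reconstruction, normalized
#'   intensity domain); with `with_cache = TRUE`, a list with `out` and the
#'   three branch caches.
#' @export
generator_forward <- function(gen, volume_input, proj_input,
                              with_cache = FALSE) {
  cfg <- gen$cfg
  vshape <- cfg$volume_shape
  if (!identical(dim(volume_input)[1:3], as.integer(vshape)))
    stop("volume input shape mismatch")
  if (!identical(dim(proj_input)[1:3], as.integer(cfg$projection_shape)))
    stop("projection input shape mismatch")
  x1 <- array(volume_input, dim = c(vshape, 1L))
  x2 <- array(proj_input, dim = c(cfg$projection_shape, 1L))
  f1 <- seq_forward(gen$vol_branch, x1)
  f2 <- seq_forward(gen$proj_branch, x2)
  z <- c(f1$out, f2$out)
  fd <- seq_forward(gen$decoder, z)
  out <- array(fd$out, dim = vshape)
  if (!with_cache) return(out)
  list(out = out, f1 = f1, f2 = f2, fd = fd, z = z)
}

# gradient of a scalar loss w.r.t. all generator parameters, given dL/d out
generator_backward <- function(gen, fw, dout) {
  bd <- seq_backward(gen$decoder, fw$fd$caches,
                     array(dout, dim = c(gen$cfg$volume_shape, 1L)))
  nz <- gen$cfg$latent_width
  b1 <- seq_backward(gen$vol_branch, fw$f1$caches, bd$dx[seq_len(nz)])
  b2 <- seq_backward(gen$proj_branch, fw$f2$caches, bd$dx[nz + seq_len(nz)])
  list(vol_branch = b1$dparams, proj_branch = b2$dparams,
       decoder = bd$dparams)
}

#' Discriminator forward pass on one patch
#'
#' @param disc a [build_discriminator()] model.
#' @param patch cubic array matching `cfg$patch_size` (channel dim of 1 is
#'   added).
#' @param with_cache keep layer caches for backpropagation.
#' @return Probability in (0, 1) that the patch is real; with caches when
#'   requested.
#' @export
discriminator_forward <- function(disc, patch, with_cache = FALSE) {
  ps <- disc$cfg$patch_size
  if (!identical(dim(patch)[1:3], as.integer(c(ps, ps, ps))))
    stop("patch shape mismatch: expected ", ps, "^3")
  x <- array(patch, dim = c(ps, ps, ps, 1L))
  fw <- seq_forward(disc$layers, x)
  if (!with_cache) return(as.numeric(fw$out))
  list(p = as.numeric(fw$out), fw = fw)
}

# backward through the discriminator from dL/dp; returns param grads and
# the gradient w.r.t. the input patch
discriminator_backward <- function(disc, fw, dp) {
  bw <- seq_backward(disc$layers, fw$caches, dp)
  list(dparams = bw$dparams,
       dx = array(bw$dx, dim = rep(disc$cfg$patch_size, 3)))
}

#' Score a whole volume with the patch discriminator
#'
#' Samples `patches_per_volume` random cubic patches (uniform corners, from
#' the current RNG stream) and returns the mean patch probability.
#'
#' @param disc a [build_discriminator()] model.
#' @param volume normalized-intensity 3D array.
#' @return Mean probability in (0, 1).
#' @export
discriminator_score <- function(disc, volume) {
  corners <- sample_patch_corners(dim(volume), disc$cfg$patch_size,
                                  disc$cfg$patches_per_volume)
  mean(vapply(seq_len(nrow(corners)), function(i) {
    p <- extract_patch(volume, corners[i, ], disc$cfg$patch_size)
    discriminator_forward(disc, p)
  }, numeric(1)))
}

sample_patch_corners <- function(vol_dim, patch_size, n) {
  if (any(vol_dim[1:3] < patch_size)) stop("patch does not fit in volume")
  hi <- vol_dim[1:3] - patch_size + 1L
  cbind(sample.int(hi[1], n, replace = TRUE),
        sample.int(hi[2], n, replace = TRUE),
        sample.int(hi[3], n, replace = TRUE))
}

extract_patch <- function(volume, corner, ps) {
  volume[corner[1]:(corner[1] + ps - 1), corner[2]:(corner[2] + ps - 1),
         corner[3]:(corner[3] + ps - 1)]
}

#' Number of trainable parameters
#'
#' @param model a `generator` or `discriminator`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "generator"))
    seq_n_params(model$vol_branch) + seq_n_params(model$proj_branch) +
      seq_n_params(model$decoder)
  else if (inherits(model, "discriminator")) seq_n_params(model$layers)
  else stop("unsupported model")
}

#' Architecture summary for introspection
#'
#' @param model a `generator` or `discriminator`.
#' @return data.frame with one row per layer: `part`, `index`, `type`,
#'   `n_params`.
#' @export
architecture_summary <- function(model) {
  parts <- if (inherits(model, "generator"))
    list(vol_branch = model$vol_branch, proj_branch = model$proj_branch,
         decoder = model$decoder)
  else list(layers = model$layers)
  do.call(rbind, lapply(names(parts), function(nm) {
    ls <- parts[[nm]]
    data.frame(part = nm, index = seq_along(ls),
               type = vapply(ls, `[[`, "", "type"),
               n_params = vapply(ls, function(l) sum(lengths(l$params)), 0))
  }))
}

# parameter-tree access across the whole generator
generator_params <- function(gen)
  list(vol_branch = seq_get_params(gen$vol_branch),
       proj_branch = seq_get_params(gen$proj_branch),
       decoder = seq_get_params(gen$decoder))

generator_set_params <- function(gen, params) {
  gen$vol_branch <- seq_set_params(gen$vol_branch, params$vol_branch)
  gen$proj_branch <- seq_set_params(gen$proj_branch, params$proj_branch)
  gen$decoder <- seq_set_params(gen$decoder, params$decoder)
  gen
}
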