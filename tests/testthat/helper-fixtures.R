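# Shared fixtures: small geometries and phantoms built in code.

desk_geometry <- function(cols = 16L, rows = 12L, px = 10)
  cone_beam_geometry(detector_cols = cols, detector_rows = rows,
                     pixel_size = px)

desk_phantom <- function(n = 32L, sp = 4, seed = 2L, noise_sd = 20)
  make_phantom(phantom_spec(grid_dims = rep(n, 3L), spacing = rep(sp, 3L),
                            noise_sd = noise_sd, seed = seed))

# analytic test volume: ramped (anti-aliased, one voxel wide) water slab of
# half-thickness `half` mm along x, on an air background
ramp_slab_volume <- function(dims = c(101L, 101L, 61L), spacing = c(2, 2, 2),
                             half = 50) {
  vol <- cbct_volume(array(-1000, dim = dims), spacing = spacing)
  xyz <- noncopcbct:::voxel_coords(vol, vol$isocenter)
  s <- spacing[1]
  w <- pmin(1, pmax(0, (half + s / 2 - abs(xyz[, 1])) / s))
  vol$voxels <- array(-1000 + 1000 * w, dim = dims)
  vol
}

# ramped water ball of radius R mm at the isocenter
ramp_ball_volume <- function(dims = c(101L, 101L, 61L), spacing = c(2, 2, 2),
                             R = 40) {
  vol <- cbct_volume(array(-1000, dim = dims), spacing = spacing)
  xyz <- noncopcbct:::voxel_coords(vol, vol$isocenter)
  s <- spacing[1]
  r <- sqrt(rowSums(xyz^2))
  w <- pmin(1, pmax(0, (R + s / 2 - r) / s))
  vol$voxels <- array(-1000 + 1000 * w, dim = dims)
  vol
}

# central detector pixel of a DRR matrix; use odd detector dims so a pixel
# center lies exactly on the source-isocenter ray
central_pixel <- function(drr) drr[(nrow(drr) + 1) / 2, (ncol(drr) + 1) / 2]

# odd-sized analytic detector: central pixel on the central ray
analytic_geometry <- function() desk_geometry(cols = 11L, rows = 9L, px = 2)

# tiny training setup reused by training/integration tests
tiny_models <- function(gseed = 3L, dseed = 4L)
  list(gen = build_generator(generator_config(base_channels = 4L,
                                              latent_width = 16L,
                                              seed = gseed)),
       disc = build_discriminator(discriminator_config(
         channels = c(4L, 8L, 8L, 8L, 8L), seed = dseed)))

tiny_dataset <- function(n_phantoms = 1L, couch = 45, repeats = 1L,
                         seed = 9L) {
  phs <- lapply(seq_len(n_phantoms), function(i)
    make_phantom(phantom_spec(grid_dims = rep(16L, 3), spacing = rep(8, 3),
                              noise_sd = 10, seed = 4L + i)))
  build_dataset(phs, couch, repeats, geometry = desk_geometry(), seed = seed)
}
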