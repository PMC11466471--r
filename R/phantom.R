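#' Digital head phantom specification
#'
#' Parameterizes a synthetic head: an ellipsoidal bony skull shell (outer
#' minus inner ellipsoid) at bone HU, brain-like soft tissue filling the
#' inner ellipsoid, spherical air cavities (sinuses), optional HU texture
#' noise, all on an air background (-1000 HU). Default semi-axes emulate an
#' adult head scaled to the grid extent.
#'
#' @param grid_dims integer length-3 voxel counts.
#' @param spacing voxel spacing in mm.
#' @param outer_semi_axes,inner_semi_axes skull ellipsoid semi-axes in mm;
#'   defaults scale to 80% / 88% of those of the grid half-extent.
#' @param bone_hu HU of the skull shell (~1200).
#' @param brain_hu HU of soft tissue (~40).
#' @param air_cavities list of `list(center = mm-offset-from-isocenter,
#'   radius = mm)` spheres set to -1000 HU; `NULL` picks two frontal sinuses.
#' @param noise_sd HU standard deviation of Gaussian texture noise inside the
#'   head (0 disables).
#' @param seed integer seed making the phantom deterministic.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_dims = c(64L, 64L, 64L), spacing = c(2, 2, 2),
                         outer_semi_axes = NULL, inner_semi_axes = NULL,
                         bone_hu = 1200, brain_hu = 40, air_cavities = NULL,
                         noise_sd = 20, seed = 0L) {
  grid_dims <- as.integer(grid_dims)
  half_extent <- (grid_dims - 1) / 2 * spacing
  # head-like anisotropy (LR < SI < AP) so all three rotations are
  # identifiable from the shape alone
  if (is.null(outer_semi_axes))
    outer_semi_axes <- c(0.68, 0.86, 0.78) * half_extent
  if (is.null(inner_semi_axes)) inner_semi_axes <- 0.88 * outer_semi_axes
  if (!all(inner_semi_axes < outer_semi_axes))
    stop("inner ellipsoid must lie strictly inside the outer one")
  if (bone_hu < -1000 || bone_hu > 3000 || brain_hu < -1000 || brain_hu > 3000)
    stop("HU levels must lie within [-1000, 3000]")
  if (is.null(air_cavities)) {
    r <- 0.12 * min(outer_semi_axes)
    off <- 0.45 * outer_semi_axes[2]
    air_cavities <- list(
      list(center = c(-0.3 * outer_semi_axes[1], off, -0.2 * outer_semi_axes[3]),
           radius = r),
      list(center = c(0.3 * outer_semi_axes[1], off, -0.2 * outer_semi_axes[3]),
           radius = r))
  }
  structure(list(grid_dims = grid_dims, spacing = as.numeric(spacing),
                 outer_semi_axes = as.numeric(outer_semi_axes),
                 inner_semi_axes = as.numeric(inner_semi_axes),
                 bone_hu = bone_hu, brain_hu = brain_hu,
                 air_cavities = air_cavities, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic digital head phantom
#'
#' Deterministic for a fixed spec (including its seed). The skull shell is at
#' `bone_hu` (>= 1000 HU by default), soft tissue near `brain_hu`, air
#' cavities and background at -1000 HU.
#'
#' @param spec a [phantom_spec()].
#' @return A [cbct_volume()].
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  d <- spec$grid_dims
  vol <- cbct_volume(array(-1000, dim = d), spacing = spec$spacing)
  xyz <- voxel_coords(vol, relative_to = vol$isocenter)
  inside <- function(semi) {
    (xyz[, 1] / semi[1])^2 + (xyz[, 2] / semi[2])^2 + (xyz[, 3] / semi[3])^2 <= 1
  }
  outer <- inside(spec$outer_semi_axes)
  inner <- inside(spec$inner_semi_axes)
  hu <- rep(-1000, nrow(xyz))
  hu[inner] <- spec$brain_hu
  hu[outer & !inner] <- spec$bone_hu
  if (spec$noise_sd > 0) {
    rng <- local_rng(spec$seed)
    noise <- rng$rnorm(sum(inner), sd = spec$noise_sd)
    hu[inner] <- hu[inner] + noise
  }
  # carve air cavities after texturing so they stay at exactly -1000 HU
  for (cav in spec$air_cavities) {
    r2 <- (xyz[, 1] - cav$center[1])^2 + (xyz[, 2] - cav$center[2])^2 +
      (xyz[, 3] - cav$center[3])^2
    hu[r2 <= cav$radius^2] <- -1000
  }
  vol$voxels <- array(pmax(hu, -1000), dim = d)
  vol
}

# Self-contained RNG stream that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    st
  }
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = with_state(stats::rnorm),
       runif = with_state(stats::runif),
       rint = with_state(function(n, max) sample.int(max, n, replace = TRUE)))
}

#' Rotate a volume to a couch position
#'
#' Rigid rotation by `couch_angle` about the room-vertical axis through the
#' isocenter. For a head-first-supine grid this is the patient
#' anterior-posterior (y) axis. Out-of-grid regions fill with air (-1000 HU).
#'
#' @param volume a [cbct_volume()].
#' @param couch_angle rotation in degrees.
#' @return A [cbct_volume()] on the same grid.
#' @export
rotate_couch <- function(volume, couch_angle) {
  apply_rigid(volume, rigid_transform(ry = couch_angle))
}

#' Uniform setup-error ranges on a discrete grid
#'
#' Translations are drawn uniformly on \[-trans_max, trans_max\] mm and
#' rotations on \[-rot_max, rot_max\] degrees, then snapped to 0.1 mm / 0.1
#' degree grids (the sampling resolution of couch corrections).
#'
#' @param trans_max maximum |translation| per axis, mm.
#' @param rot_max maximum |rotation| per axis, degrees.
#' @param trans_grid,rot_grid sampling grid resolution.
#' @return An `error_ranges` object.
#' @export
error_ranges <- function(trans_max = 10, rot_max = 3,
                         trans_grid = 0.1, rot_grid = 0.1) {
  if (trans_max <= 0 || rot_max <= 0) stop("maxima must be > 0")
  if (trans_grid <= 0 || trans_grid > trans_max ||
      rot_grid <= 0 || rot_grid > rot_max)
    stop("grids must be > 0 and <= their maxima")
  structure(list(trans_max = trans_max, rot_max = rot_max,
                 trans_grid = trans_grid, rot_grid = rot_grid),
            class = "error_ranges")
}

#' Sample a random rigid setup error
#'
#' Each of the six parameters is drawn independently from its uniform range
#' and snapped to its grid; reproducible for a fixed seed. A parameter is
#' zero only when the draw lands on the grid point zero.
#'
#' @param ranges an [error_ranges()].
#' @param seed integer seed.
#' @return A [rigid_transform()].
#' @export
sample_setup_error <- function(ranges = error_ranges(), seed = 0L) {
  rng <- local_rng(seed)
  u <- rng$runif(6)
  snap <- function(x, g) round(x / g) * g
  tr <- snap(-ranges$trans_max + 2 * ranges$trans_max * u[1:3], ranges$trans_grid)
  ro <- snap(-ranges$rot_max + 2 * ranges$rot_max * u[4:6], ranges$rot_grid)
  rigid_transform(tx = tr[1], ty = tr[2], tz = tr[3],
                  rx = ro[1], ry = ro[2], rz = ro[3])
}

#' Plan a simulated training dataset (manifest only)
#'
#' Enumerates all (phantom, couch angle, repeat) combinations with their
#' per-sample seeds and sampled setup errors, without generating any image
#' data. `nrow` of the result is `n_phantoms * length(couch_angles) * repeats`.
#'
#' @param n_phantoms number of subjects.
#' @param couch_angles couch angles in degrees.
#' @param repeats independent error draws per (subject, angle).
#' @param ranges an [error_ranges()].
#' @param seed root seed; every sample's seed is derived from it.
#' @return data.frame with columns `phantom`, `couch_angle`, `rep`, `seed`,
#'   `tx`, `ty`, `tz`, `rx`, `ry`, `rz`.
#' @export
plan_dataset <- function(n_phantoms, couch_angles, repeats,
                         ranges = error_ranges(), seed = 0L) {
  if (repeats < 1) stop("`repeats` must be >= 1")
  grid <- expand.grid(rep = seq_len(repeats), couch_angle = couch_angles,
                      phantom = seq_len(n_phantoms))
  grid <- grid[, c("phantom", "couch_angle", "rep")]
  # splittable per-sample seeds below 2^31
  grid$seed <- (as.numeric(seed) * 7919 + seq_len(nrow(grid)) * 104729) %% 2^31
  err <- t(vapply(grid$seed, function(s)
    as.numeric(sample_setup_error(ranges, seed = s)), numeric(6)))
  colnames(err) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  cbind(grid, as.data.frame(err))
}

#' Build a simulated non-coplanar training dataset
#'
#' For every row of the plan: take the subject's coplanar CBCT (the prior),
#' rotate it to the couch angle, apply the sampled rigid setup error to form
#' the ground-truth non-coplanar CBCT, and ray-cast the limited-angle
#' projection stack from that ground truth over the couch angle's arc.
#'
#' @param phantoms list of [cbct_volume()] coplanar CBCTs (one per subject).
#' @param couch_angles couch angles in degrees (must have arcs in
#'   [couch_arc()] unless `arcs` is given).
#' @param repeats error draws per (subject, angle).
#' @param geometry a [cone_beam_geometry()].
#' @param ranges an [error_ranges()].
#' @param seed root seed.
#' @param arcs optional named list mapping couch angle to [angle_range()].
#' @return List of `training_sample` objects, each with fields
#'   `coplanar_cbct`, `projections`, `ground_truth`, `couch_angle`,
#'   `setup_error`, `seed`.
#' @export
build_dataset <- function(phantoms, couch_angles, repeats,
                          geometry = cone_beam_geometry(),
                          ranges = error_ranges(), seed = 0L, arcs = NULL) {
  plan <- plan_dataset(length(phantoms), couch_angles, repeats, ranges, seed)
  lapply(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    err <- rigid_transform(row$tx, row$ty, row$tz, row$rx, row$ry, row$rz)
    cc <- phantoms[[row$phantom]]
    gt <- apply_rigid(rotate_couch(cc, row$couch_angle), err)
    arc <- if (!is.null(arcs)) arcs[[as.character(row$couch_angle)]]
           else couch_arc(row$couch_angle)
    proj <- simulate_scan(gt, geometry, arc, couch_angle = row$couch_angle)
    structure(list(coplanar_cbct = cc, projections = proj, ground_truth = gt,
                   couch_angle = row$couch_angle, setup_error = err,
                   seed = row$seed),
              class = "training_sample")
  })
}

#' Write a dataset manifest as JSON lines
#'
#' One record per sample: paths, couch angle, the six error parameters and
#' the per-sample seed.
#'
#' @param plan a data.frame from [plan_dataset()] (optionally with `path`
#'   columns added).
#' @param path output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(plan, path) {
  lines <- vapply(seq_len(nrow(plan)), function(i)
    jsonlite::toJSON(as.list(plan[i, ]), auto_unbox = TRUE, digits = NA),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
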