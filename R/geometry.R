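#' Cone-beam acquisition geometry
#'
#' Source-to-isocenter distance (SAD), source-to-detector distance (SID), the
#' flat detector grid and the gantry angle step fully determine one
#' digitally reconstructed radiograph (DRR). Defaults follow a TrueBeam-class
#' onboard imager: SAD 1000 mm, SID 1500 mm, 1024 x 768 detector, 0.388 mm
#' pixels, 0.4 degrees per frame.
#'
#' @param source_to_isocenter SAD in mm.
#' @param source_to_detector SID in mm (> SAD).
#' @param detector_cols,detector_rows detector grid size.
#' @param pixel_size isotropic detector cell size in mm.
#' @param angle_step gantry degrees per projection frame.
#' @return A `cone_beam_geometry` object.
#' @export
cone_beam_geometry <- function(source_to_isocenter = 1000,
                               source_to_detector = 1500,
                               detector_cols = 1024L, detector_rows = 768L,
                               pixel_size = 0.388, angle_step = 0.4) {
  if (!(source_to_detector > source_to_isocenter && source_to_isocenter > 0))
    stop("require source_to_detector > source_to_isocenter > 0")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  if (angle_step <= 0) stop("`angle_step` must be > 0")
  if (detector_cols < 1 || detector_rows < 1) stop("detector dims must be >= 1")
  structure(list(source_to_isocenter = source_to_isocenter,
                 source_to_detector = source_to_detector,
                 detector_cols = as.integer(detector_cols),
                 detector_rows = as.integer(detector_rows),
                 pixel_size = pixel_size, angle_step = angle_step),
            class = "cone_beam_geometry")
}

#' Gantry arc for a limited-angle scan
#'
#' Arc from `start_deg` to `end_deg` (degrees in \[0, 360)), traversed in the
#' direction of increasing angle; when `end_deg < start_deg` the arc wraps
#' through 360/0. Arc length is `(end - start) mod 360`, in (0, 360].
#'
#' @param start_deg,end_deg arc endpoints in degrees.
#' @return An `angle_range` object with fields `start_deg`, `end_deg`, `wraps`.
#' @export
angle_range <- function(start_deg, end_deg) {
  if (start_deg < 0 || start_deg >= 360 || end_deg < 0 || end_deg >= 360)
    stop("angles must lie in [0, 360)")
  structure(list(start_deg = start_deg, end_deg = end_deg,
                 wraps = end_deg < start_deg),
            class = "angle_range")
}

#' Arc length of an angle range
#' @param range an [angle_range()].
#' @return Arc length in degrees, in (0, 360].
#' @export
arc_length <- function(range) {
  len <- (range$end_deg - range$start_deg) %% 360
  if (len == 0) 360 else len
}

#' Gantry angle schedule over an arc
#'
#' Angles `a_i = (start + i * step) mod 360` on the half-open arc
#' `[start, end)`: the end angle is excluded, so an arc that is an exact
#' multiple of the step yields `arc/step` frames. The four standard
#' couch-angle arcs at 0.4 deg/frame give 375, 375, 150 and 225 projections.
#'
#' @param range an [angle_range()].
#' @param step_deg gantry degrees per frame (> 0).
#' @return Numeric vector of gantry angles in degrees, schedule order.
#' @export
projection_angles <- function(range, step_deg) {
  if (!inherits(range, "angle_range")) stop("`range` must be an angle_range")
  if (!is.finite(step_deg) || step_deg <= 0)
    stop("`step_deg` must be a positive angle")
  len <- arc_length(range)
  n <- ceiling(len / step_deg - 1e-9)  # half-open [start, end)
  (range$start_deg + (seq_len(n) - 1) * step_deg) %% 360
}

#' Couch-angle arc table for the four standard non-coplanar positions
#'
#' Collision constraints restrict the gantry arc available at each rotated
#' couch position; these are the arcs used throughout the package for couch
#' angles +45, -45, +90 and -90 degrees.
#'
#' @param couch_angle one of 45, -45, 90, -90 (degrees).
#' @return An [angle_range()].
#' @export
couch_arc <- function(couch_angle) {
  switch(as.character(couch_angle),
         "45"  = angle_range(180, 330),
         "-45" = angle_range(330, 120),
         "90"  = angle_range(250, 310),
         "-90" = angle_range(30, 120),
         stop("no arc tabulated for couch angle ", couch_angle,
              " (supported: 45, -45, 90, -90)"))
}

#' Convert HU to linear attenuation
#'
#' `mu = mu_water * (1 + HU/1000)`, clamped below at 0 (so air at -1000 HU
#' attenuates nothing).
#'
#' @param volume a [cbct_volume()] or numeric array of HU.
#' @param mu_water attenuation of water in mm^-1 (> 0); 0.02 approximates an
#'   effective ~100 kVp beam.
#' @return Numeric array of attenuation coefficients (mm^-1).
#' @export
hu_to_mu <- function(volume, mu_water = 0.02) {
  if (mu_water <= 0) stop("`mu_water` must be > 0")
  hu <- if (inherits(volume, "cbct_volume")) volume$voxels else volume
  out <- pmax(0, mu_water * (1 + hu / 1000))
  dim(out) <- dim(hu)
  out
}

#' Ray-cast a digitally reconstructed radiograph
#'
#' Casts one DRR of `volume` at gantry angle `gantry_angle`. The point source
#' moves on a circle of radius SAD about the isocenter in the plane z = iso_z
#' of the volume frame (the plane orthogonal to the couch-rotated patient
#' axis); at angle a (degrees, counter-clockwise viewed from +z) the source
#' sits at `iso + SAD * (cos a, sin a, 0)`. The flat detector is centered on
#' the source-isocenter ray at SID from the source, with columns along the
#' in-plane tangent and rows along +z. Each pixel holds the line integral
#' `integral of mu dl` (unitless) from the source to the pixel center,
#' midpoint rule with step `step_mm` (default half the minimum voxel
#' spacing), trilinear interpolation; rays that miss the grid give 0.
#'
#' @param volume a [cbct_volume()] in HU.
#' @param geometry a [cone_beam_geometry()].
#' @param gantry_angle gantry angle in degrees.
#' @param mu_water see [hu_to_mu()].
#' @param step_mm ray sampling step in mm; default `0.5 * min(spacing)`.
#' @param mu optional precomputed attenuation array (overrides `mu_water`).
#' @return `detector_rows` x `detector_cols` matrix of line integrals.
#' @export
raycast_drr <- function(volume, geometry, gantry_angle, mu_water = 0.02,
                        step_mm = NULL, mu = NULL) {
  stopifnot_volume(volume)
  if (!inherits(geometry, "cone_beam_geometry"))
    stop("`geometry` must be a cone_beam_geometry")
  if (is.null(mu)) mu <- hu_to_mu(volume, mu_water)
  if (!all(is.finite(mu))) stop("non-finite attenuation values")
  if (is.null(step_mm)) step_mm <- 0.5 * min(volume$spacing)
  a <- gantry_angle * pi / 180
  iso <- volume$isocenter
  dir <- c(cos(a), sin(a), 0)                  # iso -> source direction
  src <- iso + geometry$source_to_isocenter * dir
  det_center <- src - geometry$source_to_detector * dir
  eu <- c(-sin(a), cos(a), 0)                  # detector columns (in-plane)
  ev <- c(0, 0, 1)                             # detector rows (axial)
  cpp_raycast(mu, dim(volume$voxels), volume$spacing, volume$origin,
              src, det_center, eu, ev,
              geometry$detector_cols, geometry$detector_rows,
              geometry$pixel_size, step_mm)
}

#' Ordered stack of limited-angle projections
#'
#' @param images list of detector matrices (non-negative line integrals).
#' @param angles_deg one gantry angle per image, strictly increasing along
#'   the schedule modulo 360.
#' @param geometry the shared [cone_beam_geometry()].
#' @param couch_angle couch angle the stack was acquired at (degrees).
#' @return A `projection_set` object.
#' @export
projection_set <- function(images, angles_deg, geometry, couch_angle = 0) {
  if (length(images) != length(angles_deg))
    stop("one gantry angle per image required")
  structure(list(images = images, angles_deg = as.numeric(angles_deg),
                 geometry = geometry, couch_angle = couch_angle),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %d projections, couch %g deg, gantry %.1f..%.1f deg\n",
              length(x$images), x$couch_angle,
              x$angles_deg[1], x$angles_deg[length(x$angles_deg)]))
  invisible(x)
}

#' @export
length.projection_set <- function(x) length(x$images)

#' Simulate a limited-angle cone-beam scan
#'
#' One DRR per angle of [projection_angles()], in schedule order.
#'
#' @inheritParams raycast_drr
#' @param range an [angle_range()] (e.g. from [couch_arc()]).
#' @param couch_angle couch angle recorded in the metadata (degrees).
#' @return A [projection_set()].
#' @export
simulate_scan <- function(volume, geometry, range, couch_angle = 0,
                          mu_water = 0.02, step_mm = NULL) {
  angles <- projection_angles(range, geometry$angle_step)
  mu <- hu_to_mu(volume, mu_water)
  images <- lapply(angles, function(a)
    raycast_drr(volume, geometry, a, mu = mu, step_mm = step_mm))
  projection_set(images, angles, geometry, couch_angle)
}

#' Write / read a projection set (multi-page TIFF + JSON sidecar)
#'
#' Images are stored as 32-bit float TIFF pages in schedule order; angles,
#' geometry and couch angle go to `<path>.json`.
#'
#' @param pset a [projection_set()].
#' @param path output TIFF path.
#' @return `path` (write) or a [projection_set()] (read).
#' @export
write_projections <- function(pset, path) {
  big <- max(vapply(pset$images, max, 0), 1e-12)
  # tiff stores [0,1] floats faithfully in 32-bit mode; keep raw scale via sidecar
  tiff::writeTIFF(lapply(pset$images, function(m) m / big), path,
                  bits.per.sample = 32L)
  meta <- list(angles_deg = pset$angles_deg,
               couch_angle_deg = pset$couch_angle,
               intensity_scale = big,
               geometry = unclass(pset$geometry))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  g <- meta$geometry
  geometry <- cone_beam_geometry(g$source_to_isocenter, g$source_to_detector,
                                 g$detector_cols, g$detector_rows,
                                 g$pixel_size, g$angle_step)
  images <- lapply(pages, function(m) m * meta$intensity_scale)
  projection_set(images, meta$angles_deg, geometry, meta$couch_angle_deg)
}

#' Resample a projection stack to a fixed network input grid
#'
#' The generator's projection branch consumes a fixed (angles x rows x cols)
#' grid regardless of the arc's frame count; the stack is trilinearly
#' resampled in (angle index, row, col) space.
#'
#' @param pset a [projection_set()].
#' @param dims integer length-3: target (angles, rows, cols).
#' @return 3D array of line integrals on the target grid.
#' @export
resample_projections <- function(pset, dims = c(32L, 48L, 48L)) {
  stack <- vapply(pset$images, identity,
                  matrix(0, nrow(pset$images[[1]]), ncol(pset$images[[1]])))
  # stack dims: (rows, cols, angles) -> reorder to (angles, rows, cols)
  stack <- aperm(stack, c(3, 1, 2))
  d <- dim(stack)
  M <- diag((d - 1) / pmax(dims - 1, 1))
  cpp_resample_idx(stack, d, as.integer(dims), M, c(0, 0, 0), 0)
}
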