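#' 6-parameter rigid transform
#'
#' Rigid motion parameterized as translations `tx, ty, tz` (mm) and rotations
#' `rx, ry, rz` (degrees) about the volume x/y/z axes through the isocenter.
#' The rotation is intrinsic in the order x then y then z (matrix
#' `R = Rz %*% Ry %*% Rx`) and is applied before the translation:
#' `T(p) = R %*% (p - iso) + iso + t`.
#'
#' @param tx,ty,tz translations in mm.
#' @param rx,ry,rz rotations in degrees.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz)
  if (!all(is.finite(p))) stop("rigid transform parameters must be finite")
  structure(as.list(p), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
              x$tx, x$ty, x$tz, x$rx, x$ry, x$rz))
  invisible(x)
}

#' @export
as.numeric.rigid_transform <- function(x, ...)
  c(tx = x$tx, ty = x$ty, tz = x$tz, rx = x$rx, ry = x$ry, rz = x$rz)

rot_axis <- function(angle_deg, axis) {
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Rotation matrix of a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return 3x3 rotation matrix (intrinsic x, then y, then z).
#' @export
rotation_matrix <- function(t) {
  rot_axis(t$rz, "z") %*% rot_axis(t$ry, "y") %*% rot_axis(t$rx, "x")
}

#' Apply a rigid transform to physical points
#'
#' @param t a [rigid_transform()].
#' @param pts n x 3 matrix of points (mm).
#' @param isocenter rotation center (mm).
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(t, pts, isocenter = c(0, 0, 0)) {
  pts <- matrix(pts, ncol = 3)
  R <- rotation_matrix(t)
  sweep(pts, 2, isocenter) %*% base::t(R) +
    matrix(isocenter + c(t$tx, t$ty, t$tz), nrow(pts), 3, byrow = TRUE)
}

#' Compose two rigid transforms
#'
#' `compose_rigid(a, b)` is the transform that applies `b` first, then `a`
#' (about the same isocenter).
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_rigid <- function(a, b) {
  Ra <- rotation_matrix(a); Rb <- rotation_matrix(b)
  R <- Ra %*% Rb
  tt <- Ra %*% c(b$tx, b$ty, b$tz) + c(a$tx, a$ty, a$tz)
  rigid_from_matrix(R, as.numeric(tt))
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_rigid <- function(t) {
  R <- rotation_matrix(t)
  Rt <- base::t(R)
  rigid_from_matrix(Rt, as.numeric(-Rt %*% c(t$tx, t$ty, t$tz)))
}

# Recover (tx..rz) from rotation matrix + translation, R = Rz Ry Rx.
rigid_from_matrix <- function(R, tt) {
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock: fold everything into rz
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  }
  rigid_transform(tx = tt[1], ty = tt[2], tz = tt[3],
                  rx = rx * 180 / pi, ry = ry * 180 / pi, rz = rz * 180 / pi)
}

#' Resample a volume under a rigid transform
#'
#' The volume is moved by `t` about its isocenter and resampled onto its own
#' grid by trilinear interpolation (inverse mapping); regions transformed in
#' from outside the grid are filled with `fill` (air, -1000 HU, by default).
#' `apply_rigid(vol, rigid_transform())` returns the volume unchanged.
#'
#' @param vol a [cbct_volume()].
#' @param t a [rigid_transform()] (setup error, couch motion, ...).
#' @param fill out-of-grid fill value in HU.
#' @return A [cbct_volume()] on the same grid.
#' @export
apply_rigid <- function(vol, t, fill = -1000) {
  stopifnot_volume(vol)
  if (!inherits(t, "rigid_transform")) stop("`t` must be a rigid_transform")
  p <- as.numeric(t)
  if (all(p == 0)) return(vol)
  d <- dim(vol$voxels)
  inv <- invert_rigid(t)
  R <- rotation_matrix(inv)
  tt <- c(inv$tx, inv$ty, inv$tz)
  # output index -> output phys -> inverse transform -> input phys -> input index
  S_out <- diag(vol$spacing)
  M_phys <- R %*% S_out
  off_phys <- R %*% (vol$origin - vol$isocenter) + vol$isocenter + tt
  M <- diag(1 / vol$spacing) %*% M_phys
  off <- (as.numeric(off_phys) - vol$origin) / vol$spacing
  vox <- cpp_resample_idx(vol$voxels, dim(vol$voxels), d, M, off, fill)
  cbct_volume(vox, spacing = vol$spacing, origin = vol$origin,
              isocenter = vol$isocenter)
}
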