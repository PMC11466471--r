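#' Signed difference image
#'
#' @param gcbct,rcbct [cbct_volume()] objects on the same grid.
#' @return A [cbct_volume()] of voxelwise `gcbct - rcbct` (HU).
#' @export
difference_image <- function(gcbct, rcbct) {
  stopifnot_volume(gcbct); stopifnot_volume(rcbct)
  if (!same_grid(gcbct, rcbct)) stop("shape mismatch")
  out <- gcbct
  out$voxels <- gcbct$voxels - rcbct$voxels
  out
}

#' Root-mean-square error in HU
#'
#' `sqrt(mean((rcbct - gcbct)^2))` over the whole grid or an optional mask.
#'
#' @param gcbct,rcbct [cbct_volume()] objects on the same grid.
#' @param mask optional logical array selecting voxels (e.g. a head mask).
#' @return RMSE in HU (>= 0).
#' @export
rmse <- function(gcbct, rcbct, mask = NULL) {
  stopifnot_volume(gcbct); stopifnot_volume(rcbct)
  if (!same_grid(gcbct, rcbct)) stop("shape mismatch")
  d2 <- (rcbct$voxels - gcbct$voxels)^2
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty mask")
    d2 <- d2[mask]
  }
  sqrt(mean(d2))
}

#' Evaluation sphere point set
#'
#' Latitude-longitude grid on a sphere about the isocenter-origin: polar
#' angles `sep, 2 sep, ..., 180 - sep` crossed with azimuths
#' `0, sep, ..., 360 - sep`, plus the two poles. All points at exact radius.
#' At the default 30 mm / 5 degrees this yields 35 x 72 + 2 = 2522 points.
#'
#' @param radius sphere radius in mm.
#' @param sep angular separation in degrees (0 < sep <= 90).
#' @return A `sphere_points` object: matrix `points` (n x 3, mm), `radius`,
#'   `angular_sep`.
#' @export
sphere_points <- function(radius = 30, sep = 5) {
  if (sep <= 0 || sep > 90) stop("require 0 < sep <= 90")
  theta <- seq(sep, 180 - sep, by = sep) * pi / 180
  phi <- seq(0, 360 - sep, by = sep) * pi / 180
  g <- expand.grid(theta = theta, phi = phi)
  pts <- radius * cbind(sin(g$theta) * cos(g$phi),
                        sin(g$theta) * sin(g$phi),
                        cos(g$theta))
  pts <- rbind(pts, c(0, 0, radius), c(0, 0, -radius))
  colnames(pts) <- c("x", "y", "z")
  structure(list(points = pts, radius = radius, angular_sep = sep),
            class = "sphere_points")
}

#' Overall registration error over a sphere
#'
#' The residual rigid misalignment `T` between reconstruction and ground
#' truth is summarized as the mean Euclidean displacement of the sphere
#' points: `epsilon = mean over x in S of ||T(x) - x||`. A pure translation
#' t gives exactly `||t||` for any point set; a pure rotation by angle a
#' about an axis displaces a point at polar angle theta from that axis by
#' the chord `2 r sin(a/2) sin(theta)`.
#'
#' @param t a [rigid_transform()].
#' @param s a [sphere_points()] set.
#' @return Mean displacement in mm (>= 0).
#' @export
overall_registration_error <- function(t, s = sphere_points()) {
  moved <- transform_points(t, s$points, isocenter = c(0, 0, 0))
  mean(sqrt(rowSums((moved - s$points)^2)))
}

#' Internal rigid registration (mean-squares, multi-resolution)
#'
#' Estimates the 6-parameter rigid transform that maps `moving` onto `fixed`
#' by minimizing the mean squared intensity difference after resampling,
#' over a 3-level coarse-to-fine pyramid (Nelder-Mead at each level,
#' deterministic). The capture range is roughly +-15 mm / +-10 degrees.
#'
#' @param moving,fixed [cbct_volume()] objects on the same grid.
#' @param levels downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iteration cap per level.
#' @return A [rigid_transform()] with attributes `converged` and `objective`
#'   (final mean-squared difference).
#' @export
rigid_register <- function(moving, fixed, levels = c(4L, 2L, 1L),
                           maxit = 600L) {
  stopifnot_volume(moving); stopifnot_volume(fixed)
  if (!same_grid(moving, fixed)) stop("volumes must share a grid")
  # Optimize the fixed->moving transform (the fixed volume is resampled
  # toward the observed moving one, so the observed image is never
  # interpolated a second time), then return its inverse, the
  # moving->fixed transform the caller asked for.
  centroid <- function(v) {
    w <- as.numeric(v$voxels - min(v$voxels)) + 1e-9
    xyz <- voxel_coords(v, v$isocenter)
    colSums(xyz * w) / sum(w)
  }
  par <- c(centroid(moving) - centroid(fixed), 0, 0, 0)
  conv <- TRUE
  value <- NA_real_
  for (f in levels) {
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    obj <- function(p) {
      tr <- rigid_transform(p[1], p[2], p[3], p[4], p[5], p[6])
      mean((apply_rigid(fx, tr)$voxels - mv$voxels)^2)
    }
    # Nelder-Mead with one restart (fresh simplex) per pyramid level;
    # mm and degrees have comparable objective sensitivity at head scale
    fit <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    par <- fit$par
    conv <- conv && fit$convergence == 0
    value <- fit$value
  }
  fwd <- rigid_transform(par[1], par[2], par[3], par[4], par[5], par[6])
  out <- invert_rigid(fwd)
  attr(out, "converged") <- conv
  attr(out, "objective") <- value
  out
}

# separable 3D filtering with replicate edges, used by bone_ssim
sep_filter3 <- function(v, kern) {
  d <- dim(v)
  hw <- (length(kern) - 1) / 2
  pad_idx <- function(n) pmin(pmax(seq(1 - hw, n + hw), 1), n)
  conv_axis <- function(a, axis) {
    dd <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, dd[axis], prod(dd[-axis]))
    mp <- m[pad_idx(dd[axis]), , drop = FALSE]
    out <- matrix(0, dd[axis], ncol(m))
    for (k in seq_along(kern))
      out <- out + kern[k] * mp[(seq_len(dd[axis]) + k - 1), , drop = FALSE]
    res <- array(out, dd[perm])
    aperm(res, order(perm))
  }
  v <- conv_axis(v, 1); v <- conv_axis(v, 2); conv_axis(v, 3)
}

#' Structural similarity of thresholded bone structures
#'
#' Both volumes are hard-thresholded (intensity kept above `threshold` HU,
#' zero below) and compared with the standard structural-similarity index
#' (local Gaussian weighting, default sigma 1.5 over an 11-voxel window,
#' constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with dynamic range
#' `L = 3000` HU), averaged over the volume.
#'
#' @param gcbct,recon [cbct_volume()] objects on the same grid.
#' @param threshold bone threshold in HU.
#' @param window `"gaussian"` (default) or `"uniform"`.
#' @param window_size odd window edge length.
#' @param sigma Gaussian window standard deviation (voxels).
#' @param L dynamic range used in the stabilizing constants.
#' @return Mean SSIM in \[-1, 1\].
#' @export
bone_ssim <- function(gcbct, recon, threshold = 1000,
                      window = c("gaussian", "uniform"), window_size = 11L,
                      sigma = 1.5, L = 3000) {
  stopifnot_volume(gcbct); stopifnot_volume(recon)
  if (!same_grid(gcbct, recon)) stop("shape mismatch")
  window <- match.arg(window)
  a <- gcbct$voxels; b <- recon$voxels
  a[a < threshold] <- 0; b[b < threshold] <- 0
  if (!any(a > 0) && !any(b > 0)) stop("no voxels above the bone threshold")
  half <- (window_size - 1) / 2
  kern <- if (window == "gaussian") {
    k <- exp(-((-half:half)^2) / (2 * sigma^2)); k / sum(k)
  } else rep(1 / window_size, window_size)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_a <- sep_filter3(a, kern); mu_b <- sep_filter3(b, kern)
  va <- sep_filter3(a * a, kern) - mu_a^2
  vb <- sep_filter3(b * b, kern) - mu_b^2
  cab <- sep_filter3(a * b, kern) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(ssim_map)
}

#' Evaluate one reconstruction against its ground truth
#'
#' Computes the full metric report: RMSE, the residual rigid transform from
#' [rigid_register()] (reconstruction onto ground truth), the overall
#' registration error over the default 30 mm / 5 degree sphere, and bone
#' SSIM. Skips `bone_ssim` (NA) when neither volume has bone above threshold.
#'
#' @param sample a `training_sample` (provides the ground truth and couch
#'   angle) or a [cbct_volume()] ground truth.
#' @param reconstruction a [cbct_volume()] on the ground-truth grid.
#' @param sphere a [sphere_points()] set.
#' @return A `metrics_report` list: `rmse`, `transform` (six parameters),
#'   `epsilon`, `bone_ssim`, `couch_angle`.
#' @export
evaluate_sample <- function(sample, reconstruction,
                            sphere = sphere_points()) {
  gt <- if (inherits(sample, "training_sample")) sample$ground_truth else sample
  stopifnot_volume(gt); stopifnot_volume(reconstruction)
  tr <- rigid_register(reconstruction, gt)
  bs <- tryCatch(bone_ssim(gt, reconstruction), error = function(e) NA_real_)
  structure(list(
    rmse = rmse(gt, reconstruction),
    transform = as.numeric(tr),
    epsilon = overall_registration_error(tr, sphere),
    bone_ssim = bs,
    couch_angle = if (inherits(sample, "training_sample"))
      sample$couch_angle else NA_real_),
    class = "metrics_report")
}

#' Write / read a metrics report as JSON
#'
#' @param report a `metrics_report`.
#' @param path JSON file path.
#' @return `path` / the report.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$transform <- unlist(x$transform)
  if (is.null(x$bone_ssim)) x$bone_ssim <- NA_real_
  if (is.null(x$couch_angle)) x$couch_angle <- NA_real_
  structure(x, class = "metrics_report")
}

#' Rank-based comparison of metric groups
#'
#' Convenience wrapper for comparing a metric (RMSE, epsilon, ...) between
#' couch-angle groups with the Wilcoxon rank-sum test.
#'
#' @param x,y numeric metric values of the two groups.
#' @param paired paired test (same subjects in both groups).
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
compare_groups <- function(x, y, paired = FALSE)
  stats::wilcox.test(x, y, paired = paired, exact = FALSE)
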