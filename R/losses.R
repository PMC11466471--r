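#' Joint-loss configuration
#'
#' Tunable constants of the generator objective
#' `L = L_GAN + lambda1 * L_L1 + lambda2 * L_rigid`:
#' L1 weight `lambda1` (default 100), rigid-bone weight `lambda2` (default
#' 0.1), the soft bone-extraction threshold (1000 HU) and sigmoid steepness
#' (100000), and the number of radial central moment orders `moment_order_k`
#' (default 4).
#'
#' By default the sigmoid steepness is applied to intensities normalized to
#' \[0, 1\] over the fixed HU window \[-1000, 2000\] (so the transition width
#' is ~0.1 HU: effectively a step, but with a usable gradient everywhere).
#' `normalize = FALSE` applies the steepness to raw HU for literal fidelity.
#'
#' @param lambda1 L1 weight (>= 0).
#' @param lambda2 rigid-bone weight (>= 0).
#' @param bone_threshold bone HU threshold.
#' @param scale sigmoid steepness on the (normalized) intensity axis.
#' @param moment_order_k number of moment orders (>= 1).
#' @param normalize apply `scale` on the \[0,1\]-normalized window rather
#'   than raw HU.
#' @return A `loss_config` object.
#' @export
loss_config <- function(lambda1 = 100, lambda2 = 0.1, bone_threshold = 1000,
                        scale = 100000, moment_order_k = 4L,
                        normalize = TRUE) {
  if (lambda1 < 0 || lambda2 < 0) stop("loss weights must be >= 0")
  if (moment_order_k < 1) stop("`moment_order_k` must be >= 1")
  if (bone_threshold < -1000 || bone_threshold > 3000)
    stop("`bone_threshold` outside the HU range")
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 bone_threshold = bone_threshold, scale = scale,
                 moment_order_k = as.integer(moment_order_k),
                 normalize = normalize),
            class = "loss_config")
}

hu_window_map <- function(hu) (hu + 1000) / 3000  # [-1000, 2000] HU -> [0, 1]

#' Differentiable soft bone extraction
#'
#' `mask = sigmoid(scale * (I' - t'))` where `I'` and `t'` are the intensity
#' and the bone threshold after the configured normalization map. The mask is
#' 0.5 exactly at the threshold, saturates for HU well above/below it, is
#' monotone nondecreasing in HU and differentiable everywhere.
#'
#' @param volume a [cbct_volume()] or numeric array of HU.
#' @param cfg a [loss_config()].
#' @return Numeric array in (0, 1), same shape as the input.
#' @export
bone_soft_mask <- function(volume, cfg = loss_config()) {
  hu <- if (inherits(volume, "cbct_volume")) volume$voxels else volume
  if (!all(is.finite(hu))) stop("non-finite HU values")
  stats::plogis(bone_mask_arg(hu, cfg))
}

bone_mask_arg <- function(hu, cfg) {
  if (cfg$normalize)
    cfg$scale * (hu_window_map(hu) - hu_window_map(cfg$bone_threshold))
  else cfg$scale * (hu - cfg$bone_threshold)
}

#' Gradient of the soft bone mask with respect to HU
#'
#' @inheritParams bone_soft_mask
#' @return Array `d mask / d HU`, same shape as the input.
#' @export
bone_soft_mask_grad <- function(volume, cfg = loss_config()) {
  hu <- if (inherits(volume, "cbct_volume")) volume$voxels else volume
  s <- stats::plogis(bone_mask_arg(hu, cfg))
  chain <- if (cfg$normalize) cfg$scale / 3000 else cfg$scale
  s * (1 - s) * chain
}

sobel_kernels_3d <- function() {
  d <- c(-1, 0, 1)          # derivative along the axis
  s <- c(1, 2, 1)           # smoothing across it
  list(x = outer(d, s) %o% s,
       y = outer(s, d) %o% s,
       z = outer(s, s) %o% d)
}

# Replicate-pad a 3D array by 1 voxel; returns the padded array and the
# index map (padded voxel -> source voxel) used by the exact adjoint.
replicate_pad1 <- function(v) {
  d <- dim(v)
  ix <- pmin(pmax(0:(d[1] + 1), 1), d[1])
  iy <- pmin(pmax(0:(d[2] + 1), 1), d[2])
  iz <- pmin(pmax(0:(d[3] + 1), 1), d[3])
  idx <- as.vector(outer(outer(ix, (iy - 1) * d[1], "+"),
                         (iz - 1) * d[1] * d[2], "+"))
  list(padded = array(v[idx], dim = d + 2), idx = idx)
}

#' 3D Sobel edge magnitude
#'
#' Separable 3x3x3 Sobel kernels along each axis with replicate padding at
#' the borders; the magnitude is `sqrt(gx^2 + gy^2 + gz^2 + eps)` with a
#' small stabilizer keeping the map differentiable at zero gradient.
#'
#' @param grid 3D numeric array (dims >= 3 each).
#' @param eps stabilizer inside the square root.
#' @return List-free numeric array of edge magnitudes, same shape.
#' @export
sobel_edges <- function(grid, eps = 1e-8) {
  sobel_edges_full(grid, eps)$mag
}

# forward pass keeping intermediates needed by the backward pass
sobel_edges_full <- function(grid, eps = 1e-8) {
  if (is.null(dim(grid)) || length(dim(grid)) != 3L || any(dim(grid) < 3L))
    stop("`grid` must be a 3D array with dims >= 3")
  pad <- replicate_pad1(grid)
  dp <- c(dim(pad$padded), 1L)
  cols <- cpp_im2col(pad$padded, dp, 3L, 1L, 0L)
  kers <- sobel_kernels_3d()
  g <- lapply(kers, function(k) cols %*% as.vector(k))
  mag2 <- g$x^2 + g$y^2 + g$z^2 + eps
  mag <- array(sqrt(mag2), dim = dim(grid))
  list(mag = mag, g = g, pad_idx = pad$idx, pad_dim = dp, dim = dim(grid))
}

# adjoint: gradient of sum(dmag * mag) w.r.t. the input grid
sobel_edges_backward <- function(fwd, dmag) {
  dmag_v <- as.vector(dmag) / as.vector(fwd$mag)
  kers <- sobel_kernels_3d()
  dcols <- 0
  for (axis in names(kers))
    dcols <- dcols + (dmag_v * fwd$g[[axis]]) %*% t(as.vector(kers[[axis]]))
  dpad <- cpp_col2im(dcols, fwd$pad_dim, 3L, 1L, 0L)
  dv <- numeric(prod(fwd$dim))
  acc <- rowsum(as.vector(dpad), group = fwd$pad_idx)
  dv[as.integer(rownames(acc))] <- acc
  array(dv, dim = fwd$dim)
}

#' Rotation- and translation-invariant radial central moments
#'
#' For a nonnegative weight grid `w` with mass-weighted centroid `c`
#' (physical mm), element `j` is the order-`j` radial central moment
#' `sum(w * ||x - c||^j) / sum(w)`. Radial moments about the centroid are
#' invariant to rigid translation and rotation of the weight pattern and
#' return one scalar per order, `j = 1 .. k_max`.
#'
#' @param grid nonnegative 3D weight array.
#' @param spacing voxel spacing in mm.
#' @param k_max highest moment order.
#' @return Numeric vector of length `k_max`.
#' @export
central_moments <- function(grid, spacing = c(1, 1, 1), k_max = 4L) {
  cm <- central_moments_full(grid, spacing, k_max)
  cm$m
}

central_moments_full <- function(grid, spacing = c(1, 1, 1), k_max = 4L) {
  if (any(grid < 0)) stop("weights must be nonnegative")
  W <- sum(grid)
  if (W <= 0) stop("zero total mass (empty bone mask)")
  d <- dim(grid)
  vol <- cbct_volume(array(0, dim = d), spacing = spacing)
  xyz <- voxel_coords(vol)
  w <- as.vector(grid)
  ctr <- colSums(xyz * w) / W
  rel <- sweep(xyz, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  m <- vapply(seq_len(k_max), function(j) sum(w * r^j) / W, numeric(1))
  list(m = m, w = w, W = W, r = r, rel = rel, dim = d)
}

# d m_j / d w as arrays, j = 1..k_max (analytic, including centroid motion)
central_moments_grad <- function(cm) {
  k_max <- length(cm$m)
  r_safe <- pmax(cm$r, 1e-12)
  lapply(seq_len(k_max), function(j) {
    # v_j = sum_i w_i r_i^(j-2) (x_i - c); for j = 2 this is identically 0
    vj <- colSums(cm$w * cm$rel * r_safe^(j - 2))
    dm <- (cm$r^j - cm$m[j]) / cm$W - (j / cm$W^2) * as.vector(cm$rel %*% vj)
    array(dm, dim = cm$dim)
  })
}

#' Rigid-bone loss
#'
#' Compares the global bone-structure signature of the coplanar prior and the
#' reconstruction: each volume is passed through soft bone extraction
#' ([bone_soft_mask()]), 3D Sobel edge magnitude ([sobel_edges()]) and radial
#' central moments ([central_moments()]); the loss is the L2 norm of the
#' moment-vector difference. Because radial central moments are invariant to
#' rigid motion, the loss tolerates the large couch rotation between prior
#' and reconstruction while penalizing true shape change of the skull.
#'
#' Radial distances are measured in units of the reconstruction grid's
#' physical half-diagonal (`length_unit = "half_diagonal"`, the default), so
#' the moment vector is dimensionless and O(1) and the default weight
#' `lambda2 = 0.1` balances the other loss terms independently of grid size;
#' `length_unit = "mm"` keeps raw millimetre moments.
#'
#' @param ccbct coplanar prior, a [cbct_volume()].
#' @param recon reconstruction, a [cbct_volume()].
#' @param cfg a [loss_config()].
#' @param length_unit unit for radial distances inside the moments.
#' @return Nonnegative scalar; 0 iff the two moment vectors coincide.
#' @export
rigid_bone_loss <- function(ccbct, recon, cfg = loss_config(),
                            length_unit = c("half_diagonal", "mm")) {
  rigid_bone_loss_full(ccbct, recon, cfg, match.arg(length_unit))$loss
}

half_diagonal <- function(vol)
  0.5 * sqrt(sum(((dim(vol$voxels) - 1) * vol$spacing)^2))

rigid_bone_loss_full <- function(ccbct, recon, cfg = loss_config(),
                                 length_unit = "half_diagonal") {
  stopifnot_volume(ccbct); stopifnot_volume(recon)
  unit <- if (length_unit == "half_diagonal") half_diagonal(recon) else 1
  m_ref <- central_moments(sobel_edges(bone_soft_mask(ccbct, cfg)),
                           ccbct$spacing / unit, cfg$moment_order_k)
  mask <- bone_soft_mask(recon, cfg)
  fwd <- sobel_edges_full(mask)
  cm <- central_moments_full(fwd$mag, recon$spacing / unit,
                             cfg$moment_order_k)
  dm <- cm$m - m_ref
  list(loss = sqrt(sum(dm^2)), m_ref = m_ref, cm = cm, fwd = fwd,
       mask = mask, dm = dm)
}

#' Gradient of the rigid-bone loss with respect to the reconstruction
#'
#' Analytic backpropagation through moments, Sobel filtering and the soft
#' bone sigmoid; returns `d loss / d HU` on the reconstruction grid.
#'
#' @inheritParams rigid_bone_loss
#' @return Numeric array, same shape as `recon`.
#' @export
rigid_bone_loss_grad <- function(ccbct, recon, cfg = loss_config(),
                                 length_unit = c("half_diagonal", "mm")) {
  full <- rigid_bone_loss_full(ccbct, recon, cfg, match.arg(length_unit))
  if (full$loss == 0) return(array(0, dim = dim(recon$voxels)))
  dL_dm <- full$dm / full$loss
  grads <- central_moments_grad(full$cm)
  dmag <- 0
  for (j in seq_along(grads)) dmag <- dmag + dL_dm[j] * grads[[j]]
  dmask <- sobel_edges_backward(full$fwd, dmag)
  dmask * bone_soft_mask_grad(recon, cfg)
}

#' L1 reconstruction loss
#'
#' Mean absolute voxel difference between ground truth and reconstruction
#' (mean, not sum, so the default weights are grid-size independent).
#'
#' @param gcbct,recon [cbct_volume()] objects on the same grid, or arrays.
#' @return Nonnegative scalar.
#' @export
l1_loss <- function(gcbct, recon) {
  a <- if (inherits(gcbct, "cbct_volume")) gcbct$voxels else gcbct
  b <- if (inherits(recon, "cbct_volume")) recon$voxels else recon
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  mean(abs(a - b))
}

#' Adversarial loss terms
#'
#' Given discriminator probabilities on real and generated inputs, returns
#' the discriminator term `-[log d_real + log(1 - d_fake)]` and the
#' non-saturating generator term `-log d_fake`, each averaged over the batch.
#' With `saturating = TRUE` the generator term is the literal minimax form
#' `log(1 - d_fake)`.
#'
#' @param d_real,d_fake probabilities in (0, 1) (vectors allowed; values at
#'   exactly 0/1 are clamped by `eps`).
#' @param eps clamp keeping logs finite.
#' @param saturating use the minimax generator term instead of `-log d_fake`.
#' @return List with `generator` and `discriminator` scalars.
#' @export
gan_losses <- function(d_real, d_fake, eps = 1e-7, saturating = FALSE) {
  d_real <- pmin(1 - eps, pmax(eps, d_real))
  d_fake <- pmin(1 - eps, pmax(eps, d_fake))
  disc <- -mean(log(d_real)) - mean(log(1 - d_fake))
  gen <- if (saturating) mean(log(1 - d_fake)) else -mean(log(d_fake))
  list(generator = gen, discriminator = disc)
}

#' Joint generator objective
#'
#' `gan + lambda1 * l1 + lambda2 * rigid` with the configured weights.
#'
#' @param gan adversarial generator term.
#' @param l1 L1 term.
#' @param rigid rigid-bone term.
#' @param cfg a [loss_config()].
#' @return Scalar generator objective.
#' @export
joint_loss <- function(gan, l1, rigid, cfg = loss_config()) {
  stopifnot(is.finite(gan), is.finite(l1), is.finite(rigid))
  gan + cfg$lambda1 * l1 + cfg$lambda2 * rigid
}
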