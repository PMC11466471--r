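#' Training configuration
#'
#' Adversarial training schedule: initial learning rate 0.002 decayed by 30%
#' each epoch, with a plateau stopping rule (halt when the monitored
#' validation MSE changes by less than 5% for more than three consecutive
#' epochs). One model is trained per couch angle.
#'
#' @param lr0 initial learning rate.
#' @param lr_decay per-epoch multiplier (0 < decay < 1).
#' @param plateau_tol relative MSE variation threshold.
#' @param plateau_epochs consecutive sub-threshold epochs required beyond
#'   which training halts (halt when the count exceeds this).
#' @param max_epochs hard epoch cap.
#' @param seed training RNG seed (shuffling, patch sampling).
#' @param couch_angle couch angle this model is trained for (degrees).
#' @param g_lr_mult,d_lr_mult separate generator/discriminator learning-rate
#'   multipliers.
#' @param monitor validation monitor: `"volume"` (MSE between reconstruction
#'   and ground truth, HU^2) or `"drr"` (MSE between projections re-cast from
#'   the reconstruction and the input projections).
#' @return A `train_config` object.
#' @export
train_config <- function(lr0 = 0.002, lr_decay = 0.7, plateau_tol = 0.05,
                         plateau_epochs = 3L, max_epochs = 20L, seed = 0L,
                         couch_angle = 45, g_lr_mult = 1, d_lr_mult = 1,
                         monitor = c("volume", "drr")) {
  if (lr_decay <= 0 || lr_decay >= 1) stop("require 0 < lr_decay < 1")
  if (plateau_tol <= 0) stop("`plateau_tol` must be > 0")
  structure(list(lr0 = lr0, lr_decay = lr_decay, plateau_tol = plateau_tol,
                 plateau_epochs = as.integer(plateau_epochs),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 couch_angle = couch_angle, g_lr_mult = g_lr_mult,
                 d_lr_mult = d_lr_mult, monitor = match.arg(monitor)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `lr(epoch) = lr0 * lr_decay^epoch` (epoch 0 is the first), i.e. a 30%
#' reduction per epoch at the default decay.
#'
#' @param epoch epoch index (0-based).
#' @param cfg a [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0)) stop("`epoch` must be >= 0")
  cfg$lr0 * cfg$lr_decay^epoch
}

#' Plateau stopping rule
#'
#' Halts when the trailing consecutive relative changes of the monitored MSE
#' are all strictly below `plateau_tol` and there are more than
#' `plateau_epochs` of them.
#'
#' @param mse numeric vector of per-epoch monitored MSE values.
#' @param cfg a [train_config()].
#' @return Logical halt flag.
#' @export
stop_check <- function(mse, cfg = train_config()) {
  if (length(mse) < cfg$plateau_epochs + 1L) return(FALSE)
  rel <- abs(diff(mse)) / abs(mse[-length(mse)])
  below <- rel < cfg$plateau_tol
  run <- 0L
  for (b in rev(below)) {
    if (!b) break
    run <- run + 1L
  }
  run > cfg$plateau_epochs
}

# normalized network inputs for one training sample
sample_inputs <- function(sample, gen_cfg) {
  vol_in <- normalize_hu(sample$coplanar_cbct$voxels)
  proj <- resample_projections(sample$projections, gen_cfg$projection_shape)
  proj_in <- array(pmin(1, pmax(-1, proj / 3 - 1)), dim = dim(proj))  # line integrals ~[0, 6] -> [-1, 1]
  gt <- normalize_hu(sample$ground_truth$voxels)
  list(vol_in = vol_in, proj_in = proj_in, gt = gt)
}

# one discriminator update on a (real, fake) volume pair; returns new model,
# optimizer state, and the mean patch probabilities
disc_step <- function(disc, opt, real, fake, lr) {
  cfgd <- disc$cfg
  corners <- sample_patch_corners(dim(real), cfgd$patch_size,
                                  cfgd$patches_per_volume)
  params <- seq_get_params(disc$layers)
  grads <- NULL
  p_real <- p_fake <- numeric(nrow(corners))
  eps <- 1e-7
  for (i in seq_len(nrow(corners))) {
    fr <- discriminator_forward(disc,
            extract_patch(real, corners[i, ], cfgd$patch_size), with_cache = TRUE)
    ff <- discriminator_forward(disc,
            extract_patch(fake, corners[i, ], cfgd$patch_size), with_cache = TRUE)
    p_real[i] <- fr$p; p_fake[i] <- ff$p
    # d/dp of -[log p_real + log(1 - p_fake)] / n
    n <- nrow(corners)
    br <- discriminator_backward(disc, fr$fw,
                                 -1 / (max(fr$p, eps) * n))
    bf <- discriminator_backward(disc, ff$fw,
                                 1 / (max(1 - ff$p, eps) * n))
    g <- tree_map2(`+`, br$dparams, bf$dparams)
    grads <- if (is.null(grads)) g else tree_map2(`+`, grads, g)
  }
  st <- adam_step(params, grads, opt, lr)
  disc$layers <- seq_set_params(disc$layers, st$params)
  list(disc = disc, opt = st$state, p_real = mean(p_real),
       p_fake = mean(p_fake))
}

# one generator update; returns new model/opt plus the loss components
gen_step <- function(gen, disc, opt, inputs, ccbct, loss_cfg, lr,
                     spacing) {
  fw <- generator_forward(gen, inputs$vol_in, inputs$proj_in,
                          with_cache = TRUE)
  out <- fw$out
  n <- length(out)
  # L1 (normalized domain)
  l1 <- mean(abs(inputs$gt - out))
  dout <- sign(out - inputs$gt) / n * loss_cfg$lambda1
  # adversarial term over sampled patches
  cfgd <- disc$cfg
  corners <- sample_patch_corners(dim(out), cfgd$patch_size,
                                  cfgd$patches_per_volume)
  eps <- 1e-7
  p_fake <- numeric(nrow(corners))
  for (i in seq_len(nrow(corners))) {
    ff <- discriminator_forward(disc,
            extract_patch(out, corners[i, ], cfgd$patch_size), with_cache = TRUE)
    p_fake[i] <- ff$p
    bf <- discriminator_backward(disc, ff$fw,
                                 -1 / (max(ff$p, eps) * nrow(corners)))
    ix <- corners[i, 1]:(corners[i, 1] + cfgd$patch_size - 1)
    iy <- corners[i, 2]:(corners[i, 2] + cfgd$patch_size - 1)
    iz <- corners[i, 3]:(corners[i, 3] + cfgd$patch_size - 1)
    dout[ix, iy, iz] <- dout[ix, iy, iz] + bf$dx
  }
  gan <- -mean(log(pmax(p_fake, eps)))
  # rigid-bone term (HU domain; chain rule through denormalization)
  rigid <- 0
  if (loss_cfg$lambda2 > 0) {
    recon_vol <- cbct_volume(denormalize_hu(out), spacing = spacing)
    rigid <- rigid_bone_loss(ccbct, recon_vol, loss_cfg)
    drigid <- rigid_bone_loss_grad(ccbct, recon_vol, loss_cfg) * 1500
    dout <- dout + loss_cfg$lambda2 * drigid
  }
  grads <- generator_backward(gen, fw, dout)
  params <- generator_params(gen)
  st <- adam_step(params, grads, opt, lr)
  gen <- generator_set_params(gen, st$params)
  list(gen = gen, opt = st$state, l1 = l1, gan = gan, rigid = rigid,
       joint = joint_loss(gan, l1, rigid, loss_cfg))
}

validation_mse <- function(gen, samples, cfg, inputs = NULL) {
  if (is.null(inputs)) inputs <- lapply(samples, sample_inputs, gen_cfg = gen$cfg)
  mean(vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    inp <- inputs[[i]]
    out <- generator_forward(gen, inp$vol_in, inp$proj_in)
    if (cfg$monitor == "drr") {
      recon <- s$ground_truth
      recon$voxels <- denormalize_hu(out)
      geom <- s$projections$geometry
      mean(vapply(seq_along(s$projections$angles_deg), function(i) {
        drr <- raycast_drr(recon, geom, s$projections$angles_deg[i])
        mean((drr - s$projections$images[[i]])^2)
      }, numeric(1)))
    } else {
      mean((denormalize_hu(out) - s$ground_truth$voxels)^2)
    }
  }, numeric(1)))
}

#' Adversarial training loop
#'
#' Alternating discriminator/generator updates (one each per sample step)
#' with the configured learning-rate decay and plateau stopping. The
#' checkpoint of the epoch with the best validation MSE is returned.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param dataset list of training samples from [build_dataset()]; samples
#'   should share `cfg$couch_angle`.
#' @param gen a [build_generator()] model.
#' @param disc a [build_discriminator()] model.
#' @param loss_cfg a [loss_config()].
#' @param cfg a [train_config()].
#' @param val_dataset optional held-out samples for the validation monitor
#'   (defaults to the training set).
#' @param n_steps optional cap on total optimizer steps (smoke tests).
#' @return List with `checkpoint` (best-MSE model state) and `history`
#'   (data.frame: epoch, lr, l1, gan, rigid, joint, d_loss, p_real, p_fake,
#'   val_mse, seconds).
#' @export
train <- function(dataset, gen, disc, loss_cfg = loss_config(),
                  cfg = train_config(), val_dataset = NULL, n_steps = NULL) {
  if (!length(dataset)) stop("empty dataset")
  if (is.null(val_dataset)) val_dataset <- dataset
  set.seed(cfg$seed)
  g_opt <- adam_init(generator_params(gen))
  d_opt <- adam_init(seq_get_params(disc$layers))
  history <- NULL
  best <- list(mse = Inf, checkpoint = NULL)
  steps <- 0L
  spacing <- dataset[[1]]$ground_truth$spacing
  inputs_list <- lapply(dataset, sample_inputs, gen_cfg = gen$cfg)
  val_inputs <- lapply(val_dataset, sample_inputs, gen_cfg = gen$cfg)
  for (epoch in seq_len(cfg$max_epochs) - 1L) {
    t0 <- proc.time()[["elapsed"]]
    lr <- lr_schedule(epoch, cfg)
    order_ <- sample.int(length(dataset))
    comp <- c(l1 = 0, gan = 0, rigid = 0, joint = 0, d_loss = 0,
              p_real = 0, p_fake = 0)
    nsamp <- 0L
    for (si in order_) {
      s <- dataset[[si]]
      inp <- inputs_list[[si]]
      fake <- generator_forward(gen, inp$vol_in, inp$proj_in)
      ds <- disc_step(disc, d_opt, inp$gt, fake, lr * cfg$d_lr_mult)
      disc <- ds$disc; d_opt <- ds$opt
      gs <- gen_step(gen, disc, g_opt, inp, s$coplanar_cbct, loss_cfg,
                     lr * cfg$g_lr_mult, spacing)
      gen <- gs$gen; g_opt <- gs$opt
      if (!all(is.finite(c(gs$joint, gs$l1, gs$gan, gs$rigid))))
        stop(sprintf("non-finite loss at epoch %d (l1=%g gan=%g rigid=%g)",
                     epoch, gs$l1, gs$gan, gs$rigid))
      dl <- gan_losses(ds$p_real, ds$p_fake)$discriminator
      comp <- comp + c(gs$l1, gs$gan, gs$rigid, gs$joint, dl,
                       ds$p_real, ds$p_fake)
      nsamp <- nsamp + 1L
      steps <- steps + 1L
      if (!is.null(n_steps) && steps >= n_steps) break
    }
    comp <- comp / nsamp
    mse <- validation_mse(gen, val_dataset, cfg, val_inputs)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, l1 = comp["l1"], gan = comp["gan"],
      rigid = comp["rigid"], joint = comp["joint"], d_loss = comp["d_loss"],
      p_real = comp["p_real"], p_fake = comp["p_fake"], val_mse = mse,
      seconds = proc.time()[["elapsed"]] - t0, row.names = NULL))
    if (comp["p_real"] <= 0.05 || comp["p_real"] >= 0.95)
      message(sprintf("epoch %d: discriminator real-accuracy %.3f outside (0.05, 0.95)",
                      epoch, comp["p_real"]))
    if (mse < best$mse)
      best <- list(mse = mse,
                   checkpoint = make_checkpoint(gen, disc, loss_cfg, cfg,
                                                epoch, history, g_opt, d_opt))
    if (!is.null(n_steps) && steps >= n_steps) break
    if (stop_check(history$val_mse, cfg)) break
  }
  last <- make_checkpoint(gen, disc, loss_cfg, cfg, history$epoch[nrow(history)],
                          history, g_opt, d_opt)
  list(checkpoint = best$checkpoint, last = last, history = history)
}

make_checkpoint <- function(gen, disc, loss_cfg, cfg, epoch, history,
                            g_opt, d_opt) {
  structure(list(generator = gen, discriminator = disc, loss_cfg = loss_cfg,
                 train_cfg = cfg, epoch = epoch, history = history,
                 g_opt = g_opt, d_opt = d_opt,
                 couch_angle = cfg$couch_angle,
                 rng_state = get(".Random.seed", globalenv())),
            class = "cbct_checkpoint")
}

#' Save / load a training checkpoint
#'
#' Checkpoints carry the full model weights, both optimizer states, configs,
#' training history and the RNG state, so training can resume exactly.
#'
#' @param ckpt a `cbct_checkpoint`.
#' @param path file path (`.rds`).
#' @return `path` (save) / the checkpoint (load).
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Resume training from a checkpoint
#'
#' Restores models, optimizer states and the RNG state, then continues for
#' `extra_epochs` more epochs; with the saved RNG state the continuation
#' reproduces exactly what an uninterrupted run would have done.
#'
#' @param ckpt a `cbct_checkpoint` (typically `result$last`).
#' @param dataset,val_dataset as in [train()].
#' @param extra_epochs additional epochs to run.
#' @return As [train()].
#' @export
resume_train <- function(ckpt, dataset, val_dataset = NULL,
                         extra_epochs = 1L) {
  cfg <- ckpt$train_cfg
  if (is.null(val_dataset)) val_dataset <- dataset
  gen <- ckpt$generator; disc <- ckpt$discriminator
  g_opt <- ckpt$g_opt; d_opt <- ckpt$d_opt
  assign(".Random.seed", ckpt$rng_state, globalenv())
  history <- ckpt$history
  best <- list(mse = Inf, checkpoint = NULL)
  spacing <- dataset[[1]]$ground_truth$spacing
  inputs_list <- lapply(dataset, sample_inputs, gen_cfg = gen$cfg)
  val_inputs <- lapply(val_dataset, sample_inputs, gen_cfg = gen$cfg)
  start_epoch <- ckpt$epoch + 1L
  for (epoch in start_epoch:(start_epoch + extra_epochs - 1L)) {
    t0 <- proc.time()[["elapsed"]]
    lr <- lr_schedule(epoch, cfg)
    order_ <- sample.int(length(dataset))
    comp <- c(l1 = 0, gan = 0, rigid = 0, joint = 0, d_loss = 0,
              p_real = 0, p_fake = 0)
    for (si in order_) {
      s <- dataset[[si]]
      inp <- inputs_list[[si]]
      fake <- generator_forward(gen, inp$vol_in, inp$proj_in)
      ds <- disc_step(disc, d_opt, inp$gt, fake, lr * cfg$d_lr_mult)
      disc <- ds$disc; d_opt <- ds$opt
      gs <- gen_step(gen, disc, g_opt, inp, s$coplanar_cbct, loss_cfg = ckpt$loss_cfg,
                     lr = lr * cfg$g_lr_mult, spacing = spacing)
      gen <- gs$gen; g_opt <- gs$opt
      dl <- gan_losses(ds$p_real, ds$p_fake)$discriminator
      comp <- comp + c(gs$l1, gs$gan, gs$rigid, gs$joint, dl,
                       ds$p_real, ds$p_fake)
    }
    comp <- comp / length(dataset)
    mse <- validation_mse(gen, val_dataset, cfg, val_inputs)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, l1 = comp["l1"], gan = comp["gan"],
      rigid = comp["rigid"], joint = comp["joint"], d_loss = comp["d_loss"],
      p_real = comp["p_real"], p_fake = comp["p_fake"], val_mse = mse,
      seconds = proc.time()[["elapsed"]] - t0, row.names = NULL))
    if (mse < best$mse)
      best <- list(mse = mse,
                   checkpoint = make_checkpoint(gen, disc, ckpt$loss_cfg, cfg,
                                                epoch, history, g_opt, d_opt))
  }
  last <- make_checkpoint(gen, disc, ckpt$loss_cfg, cfg,
                          history$epoch[nrow(history)], history, g_opt, d_opt)
  list(checkpoint = best$checkpoint, last = last, history = history)
}

#' Reconstruct a non-coplanar CBCT with a trained generator
#'
#' Application stage: the coplanar prior and the limited-angle projection
#' stack are fed to the trained generator; the output is denormalized to HU
#' on the prior's grid. The checkpoint's couch angle must match the
#' projection stack's.
#'
#' @param ckpt a `cbct_checkpoint`.
#' @param ccbct coplanar prior [cbct_volume()].
#' @param projections a [projection_set()].
#' @return A [cbct_volume()] reconstruction.
#' @export
reconstruct <- function(ckpt, ccbct, projections) {
  gen <- ckpt$generator
  if (!isTRUE(all.equal(ckpt$couch_angle, projections$couch_angle)))
    stop(sprintf("checkpoint couch angle (%g) does not match projections (%g)",
                 ckpt$couch_angle, projections$couch_angle))
  if (!identical(dim(ccbct$voxels), as.integer(gen$cfg$volume_shape)))
    stop("prior volume shape does not match the checkpoint's generator")
  vol_in <- normalize_hu(ccbct$voxels)
  proj <- resample_projections(projections, gen$cfg$projection_shape)
  proj_in <- array(pmin(1, pmax(-1, proj / 3 - 1)), dim = dim(proj))
  out <- generator_forward(gen, vol_in, proj_in)
  cbct_volume(denormalize_hu(out), spacing = ccbct$spacing,
              origin = ccbct$origin, isocenter = ccbct$isocenter)
}
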