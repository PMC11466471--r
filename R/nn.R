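# Minimal 3D neural-network layer library: plain-list layers with explicit
# forward/backward passes, built on the package's im2col/col2im kernels.
# Tensors are R arrays (nx, ny, nz, channels); dense activations are numeric
# vectors. Every layer returns its cache from the forward pass so the
# backward pass is exact.

nn_rng <- function(seed) local_rng(seed)

he_init <- function(rng, n, fan_in) rng$rnorm(n, sd = sqrt(2 / fan_in))

layer_conv3 <- function(rng, in_ch, out_ch, stride = 1L, ksize = 3L) {
  W <- array(he_init(rng, ksize^3 * in_ch * out_ch, ksize^3 * in_ch),
             dim = c(ksize, ksize, ksize, in_ch, out_ch))
  list(type = "conv3", in_ch = in_ch, out_ch = out_ch, stride = as.integer(stride),
       ksize = as.integer(ksize), pad = as.integer((ksize - 1) / 2),
       params = list(W = W, b = numeric(out_ch)))
}

layer_bn <- function(channels, eps = 1e-5) {
  list(type = "bn", channels = channels, eps = eps,
       params = list(gamma = rep(1, channels), beta = numeric(channels)))
}

layer_prelu <- function(init_slope = 0.25) {
  list(type = "prelu", params = list(a = init_slope))
}

layer_maxpool <- function() list(type = "maxpool", params = list())

layer_flatten <- function() list(type = "flatten", params = list())

layer_reshape <- function(out_dim) {
  list(type = "reshape", out_dim = as.integer(out_dim), params = list())
}

layer_dense <- function(rng, n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = matrix(he_init(rng, n_in * n_out, n_in), n_in, n_out),
                     b = numeric(n_out)))
}

# transposed convolution, kernel 2x2x2, stride 2 (non-overlapping upsampling)
layer_deconv2 <- function(rng, in_ch, out_ch) {
  list(type = "deconv2", in_ch = in_ch, out_ch = out_ch,
       params = list(W = matrix(he_init(rng, in_ch * 8 * out_ch, in_ch),
                                in_ch, 8 * out_ch),
                     b = numeric(out_ch)))
}

layer_sigmoid <- function() list(type = "sigmoid", params = list())

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv3 = {
      d <- dim(x)
      cols <- cpp_im2col(x, d, layer$ksize, layer$stride, layer$pad)
      Wm <- matrix(layer$params$W, ncol = layer$out_ch)
      out_m <- cols %*% Wm
      out_m <- sweep(out_m, 2, layer$params$b, "+")
      os <- (d[1:3] + 2 * layer$pad - layer$ksize) %/% layer$stride + 1L
      list(out = array(out_m, dim = c(os, layer$out_ch)),
           cache = list(cols = cols, in_dim = d, out_sp = os))
    },
    bn = {
      d <- dim(x)
      nsp <- prod(d[1:3])
      xm <- matrix(x, nsp, d[4])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc^2)
      istd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(xc, 2, istd, "*")
      out <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2,
                   layer$params$beta, "+")
      list(out = array(out, dim = d),
           cache = list(xhat = xhat, istd = istd, dim = d, nsp = nsp))
    },
    prelu = {
      a <- layer$params$a
      neg <- x < 0
      out <- x
      out[neg] <- a * x[neg]
      list(out = out, cache = list(x = x, neg = neg))
    },
    maxpool = {
      mp <- cpp_maxpool2(x, dim(x))
      list(out = mp$out, cache = list(argmax = mp$argmax, in_dim = dim(x)))
    },
    flatten = list(out = as.vector(x), cache = list(in_dim = dim(x))),
    reshape = list(out = array(x, dim = layer$out_dim),
                   cache = list(in_len = length(x))),
    dense = {
      xv <- as.vector(x)
      list(out = as.vector(xv %*% layer$params$W) + layer$params$b,
           cache = list(x = xv))
    },
    deconv2 = {
      d <- dim(x)
      Xm <- matrix(x, prod(d[1:3]), d[4])
      Ym <- Xm %*% layer$params$W   # (N, 8*out_ch), offset-fastest
      os <- 2L * d[1:3]
      out <- array(0, dim = c(os, layer$out_ch))
      for (oc in seq_len(layer$out_ch)) {
        for (off in 0:7) {
          dx <- off %% 2; dy <- (off %/% 2) %% 2; dz <- off %/% 4
          out[seq(1 + dx, os[1], 2), seq(1 + dy, os[2], 2),
              seq(1 + dz, os[3], 2), oc] <-
            array(Ym[, (oc - 1) * 8 + off + 1], dim = d[1:3]) +
            layer$params$b[oc]
        }
      }
      list(out = out, cache = list(Xm = Xm, in_dim = d))
    },
    sigmoid = {
      s <- 1 / (1 + exp(-x))
      list(out = s, cache = list(s = s))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv3 = {
      dm <- matrix(dout, ncol = layer$out_ch)
      Wm <- matrix(layer$params$W, ncol = layer$out_ch)
      dW <- crossprod(cache$cols, dm)
      db <- colSums(dm)
      dcols <- tcrossprod(dm, Wm)
      dx <- cpp_col2im(dcols, cache$in_dim, layer$ksize, layer$stride, layer$pad)
      list(dx = dx, dparams = list(W = array(dW, dim = dim(layer$params$W)),
                                   b = db))
    },
    bn = {
      d <- cache$dim
      dm <- matrix(dout, cache$nsp, d[4])
      dgamma <- colSums(dm * cache$xhat)
      dbeta <- colSums(dm)
      dxhat <- sweep(dm, 2, layer$params$gamma, "*")
      n <- cache$nsp
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
      dx <- sweep(t1 - t2, 2, cache$istd, "*")
      list(dx = array(dx, dim = d),
           dparams = list(gamma = dgamma, beta = dbeta))
    },
    prelu = {
      a <- layer$params$a
      dx <- dout
      dx[cache$neg] <- a * dout[cache$neg]
      da <- sum(dout[cache$neg] * cache$x[cache$neg])
      list(dx = dx, dparams = list(a = da))
    },
    maxpool = {
      dx <- numeric(prod(cache$in_dim))
      dx[cache$argmax] <- as.vector(dout)
      list(dx = array(dx, dim = cache$in_dim), dparams = list())
    },
    flatten = list(dx = array(dout, dim = cache$in_dim), dparams = list()),
    reshape = list(dx = as.vector(dout), dparams = list()),
    dense = {
      dW <- outer(cache$x, as.vector(dout))
      db <- as.vector(dout)
      dx <- as.vector(layer$params$W %*% as.vector(dout))
      list(dx = dx, dparams = list(W = dW, b = db))
    },
    deconv2 = {
      d <- cache$in_dim
      os <- 2L * d[1:3]
      dYm <- matrix(0, prod(d[1:3]), 8 * layer$out_ch)
      db <- numeric(layer$out_ch)
      for (oc in seq_len(layer$out_ch)) {
        for (off in 0:7) {
          dx_ <- off %% 2; dy_ <- (off %/% 2) %% 2; dz_ <- off %/% 4
          blk <- dout[seq(1 + dx_, os[1], 2), seq(1 + dy_, os[2], 2),
                      seq(1 + dz_, os[3], 2), oc]
          dYm[, (oc - 1) * 8 + off + 1] <- as.vector(blk)
          db[oc] <- db[oc] + sum(blk)
        }
      }
      dW <- crossprod(cache$Xm, dYm)
      dx <- array(tcrossprod(dYm, layer$params$W), dim = d)
      list(dx = dx, dparams = list(W = dW, b = db))
    },
    sigmoid = list(dx = dout * cache$s * (1 - cache$s), dparams = list()),
    stop("unknown layer type: ", layer$type))
}

seq_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], x)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, caches, dout) {
  dparams <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- bw$dx
    dparams[[i]] <- bw$dparams
  }
  list(dx = dout, dparams = dparams)
}

seq_n_params <- function(layers)
  sum(vapply(layers, function(l) sum(lengths(l$params)), 0))

# --- parameter-tree utilities (nested lists of numeric arrays) -------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(el) tree_map(f, el)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

seq_get_params <- function(layers) lapply(layers, function(l) l$params)

seq_set_params <- function(layers, params) {
  for (i in seq_along(layers)) layers[[i]]$params <- params[[i]]
  layers
}

# --- Adam optimizer over parameter trees -----------------------------------

adam_init <- function(params)
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
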