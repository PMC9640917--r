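# Minimal feed-forward layer framework with explicit forward/backward passes.
#
# Activations are dense arrays in R's column-major layout:
#   spatial maps  H x W x C x N,   pooled features  N x C.
# Each layer is a plain list carrying its `type`, hyperparameters and a
# (possibly nested) `params` list of numeric arrays.  `nn_forward()` returns
# the output plus a cache, `nn_backward()` consumes the cache and the output
# gradient and returns the input gradient plus parameter gradients shaped
# like `params`.  Convolutions call the compiled im2col/GEMM kernels.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' @noRd
nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(
    type = "conv", stride = as.integer(stride), pad = as.integer(pad),
    params = list(
      w = he_init(c(k, k, in_ch, out_ch), fan_in = k * k * in_ch),
      b = numeric(out_ch)
    )
  )
}

nn_relu <- function() list(type = "relu", params = NULL)

nn_gap <- function() list(type = "gap", params = NULL)

nn_linear <- function(in_dim, out_dim, bias = TRUE) {
  params <- list(w = he_init(c(in_dim, out_dim), fan_in = in_dim))
  if (bias) params$b <- numeric(out_dim)
  list(type = "linear", params = params)
}

nn_l2norm <- function() list(type = "l2norm", params = NULL)

# 1D batch normalisation over pooled feature vectors (N x C).  Pooled
# features of small-sample image batches are a large shared component plus
# tiny per-sample fluctuations; standardising them is what makes both the
# metric and the classification objectives see the fluctuations.  Batch
# statistics are used while training (and returned so the training loop can
# commit the running averages); running statistics serve inference.
nn_bnorm <- function(dim, momentum = 0.1, eps = 1e-5) {
  list(type = "bnorm", momentum = momentum, eps = eps,
       run_mean = numeric(dim), run_var = rep(1, dim),
       params = list(gamma = rep(1, dim), beta = numeric(dim)))
}

bnorm_forward <- function(layer, x, train) {
  p <- layer$params
  if (train && nrow(x) > 1) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(x, 2, mu), 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(out = y,
       cache = if (train) list(xhat = xhat, istd = istd),
       bn_stats = if (train && nrow(x) > 1) list(mean = mu, var = v))
}

bnorm_backward <- function(layer, cache, dout) {
  g <- layer$params$gamma
  xhat <- cache$xhat
  n <- nrow(xhat)
  dxhat <- sweep(dout, 2, g, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- sweep(n * dxhat, 2, s1) - sweep(xhat, 2, s2, `*`)
  dx <- sweep(dx, 2, cache$istd / n, `*`)
  list(dx = dx, grads = list(gamma = colSums(dout * xhat),
                             beta = colSums(dout)))
}

# Fold freshly computed batch statistics into the running averages; called
# by the training loops after each training-mode forward pass.
net_commit_bn <- function(layers, bn_stats) {
  for (i in seq_along(bn_stats)) {
    st <- bn_stats[[i]]
    if (is.null(st)) next
    m <- layers[[i]]$momentum
    layers[[i]]$run_mean <- (1 - m) * layers[[i]]$run_mean + m * st$mean
    layers[[i]]$run_var <- (1 - m) * layers[[i]]$run_var + m * st$var
  }
  layers
}

# Channel gate layers -------------------------------------------------------

# Squeeze-and-excitation bottleneck producing one multiplicative gate per
# channel and sample.  `prior` enters as an additive log(p_c / mean(p)) bias
# on the gate logits so that only the ratios of the prior weights matter;
# `learn_bias` adds a free per-channel logit offset (used by MAWM so the
# network can relearn channel contributions away from the prior).
nn_gate <- function(channels, r = 8L, prior = NULL, learn_bias = FALSE,
                    type = "se") {
  hidden <- max(1L, as.integer(ceiling(channels / r)))
  params <- list(
    w1 = he_init(c(channels, hidden), fan_in = channels),
    b1 = numeric(hidden),
    w2 = array(0, c(hidden, channels)), # zero init: gates start at sigmoid(bias)
    b2 = numeric(channels)
  )
  if (learn_bias) params$beta <- numeric(channels)
  prior_bias <- if (is.null(prior)) numeric(channels) else prior_log_bias(prior)
  list(type = type, channels = channels, prior_bias = prior_bias,
       learn_bias = learn_bias, force_gates = NULL, params = params)
}

nn_se <- function(channels, r = 8L) nn_gate(channels, r)

nn_mawm <- function(channels, r = 2L, prior = NULL) {
  nn_gate(channels, r = r, prior = prior, learn_bias = TRUE, type = "mawm")
}

# Efficient channel attention: a shared 1D convolution of width `k` across
# the channel axis of the squeezed descriptor replaces the SE bottleneck.
nn_eca <- function(channels, k = 3L) {
  list(type = "eca", channels = channels, k = as.integer(k),
       force_gates = NULL, params = list(wk = numeric(k)))
}

# Residual block: conv-relu-conv (+ optional channel gate) + shortcut, relu.
nn_resblock <- function(in_ch, out_ch, stride = 1L,
                        attn = c("none", "se", "eca"), r = 8L) {
  attn <- match.arg(attn)
  blk <- list(
    type = "resblock",
    conv1 = nn_conv(in_ch, out_ch, stride = stride),
    conv2 = nn_conv(out_ch, out_ch),
    gate = switch(attn, none = NULL, se = nn_se(out_ch, r), eca = nn_eca(out_ch)),
    shortcut = if (stride != 1L || in_ch != out_ch) {
      nn_conv(in_ch, out_ch, k = 1L, stride = stride, pad = 0L)
    }
  )
  blk$params <- list(
    conv1 = blk$conv1$params, conv2 = blk$conv2$params,
    gate = if (!is.null(blk$gate)) blk$gate$params,
    shortcut = if (!is.null(blk$shortcut)) blk$shortcut$params
  )
  blk
}

prior_log_bias <- function(prior) {
  stopifnot(all(is.finite(prior)), all(prior >= 0), any(prior > 0))
  log(pmax(prior, 1e-12) / mean(prior))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Broadcast a per-(sample, channel) factor over the spatial grid of x.
scale_channels <- function(x, g) {
  d <- dim(x)
  x * rep(as.vector(t(g)), each = d[1] * d[2])
}

channel_means <- function(x) {
  d <- dim(x)
  t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

# Forward / backward dispatch ----------------------------------------------

nn_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      p <- layer$params
      y <- .conv2d_forward(x, p$w, p$b, layer$stride, layer$pad)
      list(out = y, cache = if (train) list(x = x))
    },
    relu = {
      y <- pmax(x, 0)
      if (!is.null(dim(x))) dim(y) <- dim(x)
      list(out = y, cache = if (train) list(pos = x > 0))
    },
    gap = {
      s <- channel_means(x)
      list(out = s, cache = if (train) list(dims = dim(x)))
    },
    linear = {
      p <- layer$params
      y <- x %*% p$w
      if (!is.null(p$b)) y <- y + matrix(p$b, nrow(x), length(p$b), byrow = TRUE)
      list(out = y, cache = if (train) list(x = x))
    },
    l2norm = {
      r <- sqrt(rowSums(x^2)) + 1e-12
      y <- x / r
      list(out = y, cache = if (train) list(y = y, r = r))
    },
    bnorm = bnorm_forward(layer, x, train),
    se = ,
    mawm = gate_forward_se(layer, x, train),
    eca = gate_forward_eca(layer, x, train),
    resblock = resblock_forward(layer, x, train),
    stop("unknown layer type: ", layer$type)
  )
}

nn_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      g <- .conv2d_backward(cache$x, layer$params$w, dout, layer$stride, layer$pad)
      list(dx = g$dx, grads = list(w = g$dw, b = as.numeric(g$db)))
    },
    relu = {
      dx <- dout * cache$pos
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$dims
      dx <- rep(as.vector(t(dout)) / (d[1] * d[2]), each = d[1] * d[2])
      dim(dx) <- d
      list(dx = dx, grads = NULL)
    },
    linear = {
      g <- list(w = t(cache$x) %*% dout)
      if (!is.null(layer$params$b)) g$b <- colSums(dout)
      list(dx = dout %*% t(layer$params$w), grads = g)
    },
    l2norm = {
      y <- cache$y
      dx <- (dout - y * rowSums(dout * y)) / cache$r
      list(dx = dx, grads = NULL)
    },
    bnorm = bnorm_backward(layer, cache, dout),
    se = ,
    mawm = gate_backward_se(layer, cache, dout),
    eca = gate_backward_eca(layer, cache, dout),
    resblock = resblock_backward(layer, cache, dout),
    stop("unknown layer type: ", layer$type)
  )
}

# SE / MAWM gate ------------------------------------------------------------

gate_forward_se <- function(layer, x, train) {
  p <- layer$params
  s <- channel_means(x)                                    # N x C squeeze
  if (!is.null(layer$force_gates)) {
    g <- matrix(layer$force_gates, nrow(s), layer$channels, byrow = TRUE)
    y <- scale_channels(x, g)
    return(list(out = y, gates = g,
                cache = if (train) list(x = x, g = g, forced = TRUE)))
  }
  z1 <- s %*% p$w1 + matrix(p$b1, nrow(s), length(p$b1), byrow = TRUE)
  a1 <- pmax(z1, 0)
  logit <- a1 %*% p$w2 + matrix(p$b2, nrow(s), layer$channels, byrow = TRUE)
  logit <- logit + matrix(layer$prior_bias, nrow(s), layer$channels, byrow = TRUE)
  if (layer$learn_bias) {
    logit <- logit + matrix(p$beta, nrow(s), layer$channels, byrow = TRUE)
  }
  g <- sigmoid(logit)
  y <- scale_channels(x, g)
  list(out = y, gates = g,
       cache = if (train) list(x = x, s = s, z1 = z1, a1 = a1, g = g,
                               forced = FALSE))
}

gate_backward_se <- function(layer, cache, dout) {
  p <- layer$params
  x <- cache$x
  g <- cache$g
  d <- dim(x)
  hw <- d[1] * d[2]
  dx <- scale_channels(dout, g)
  dg <- t(matrix(colSums(matrix(dout * x, hw, d[3] * d[4])), d[3], d[4]))
  if (isTRUE(cache$forced)) {
    return(list(dx = dx, grads = rapply(p, function(a) a * 0, how = "replace")))
  }
  dlogit <- dg * g * (1 - g)
  da1 <- dlogit %*% t(p$w2)
  dz1 <- da1 * (cache$z1 > 0)
  ds <- dz1 %*% t(p$w1)
  dx_s <- rep(as.vector(t(ds)) / hw, each = hw)
  dim(dx_s) <- d
  grads <- list(
    w1 = t(cache$s) %*% dz1, b1 = colSums(dz1),
    w2 = t(cache$a1) %*% dlogit, b2 = colSums(dlogit)
  )
  if (layer$learn_bias) grads$beta <- colSums(dlogit)
  list(dx = dx + dx_s, grads = grads)
}

# ECA gate -------------------------------------------------------------------

eca_conv1d <- function(s, wk) {
  k <- length(wk)
  half <- (k - 1L) %/% 2L
  C <- ncol(s)
  out <- matrix(0, nrow(s), C)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    out[, ok] <- out[, ok] + wk[j] * s[, src[ok]]
  }
  out
}

gate_forward_eca <- function(layer, x, train) {
  s <- channel_means(x)
  if (!is.null(layer$force_gates)) {
    g <- matrix(layer$force_gates, nrow(s), layer$channels, byrow = TRUE)
    return(list(out = scale_channels(x, g), gates = g,
                cache = if (train) list(x = x, g = g, forced = TRUE)))
  }
  logit <- eca_conv1d(s, layer$params$wk)
  g <- sigmoid(logit)
  list(out = scale_channels(x, g), gates = g,
       cache = if (train) list(x = x, s = s, g = g, forced = FALSE))
}

gate_backward_eca <- function(layer, cache, dout) {
  x <- cache$x
  g <- cache$g
  d <- dim(x)
  hw <- d[1] * d[2]
  dx <- scale_channels(dout, g)
  dg <- t(matrix(colSums(matrix(dout * x, hw, d[3] * d[4])), d[3], d[4]))
  if (isTRUE(cache$forced)) {
    return(list(dx = dx, grads = list(wk = numeric(layer$k))))
  }
  dlogit <- dg * g * (1 - g)
  k <- layer$k
  half <- (k - 1L) %/% 2L
  C <- ncol(dg)
  s <- cache$s
  dwk <- numeric(k)
  ds <- matrix(0, nrow(s), C)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    dwk[j] <- sum(dlogit[, ok] * s[, src[ok]])
    ds[, src[ok]] <- ds[, src[ok]] + layer$params$wk[j] * dlogit[, ok]
  }
  dx_s <- rep(as.vector(t(ds)) / hw, each = hw)
  dim(dx_s) <- d
  list(dx = dx + dx_s, grads = list(wk = dwk))
}

# Residual block --------------------------------------------------------------

sync_block_params <- function(layer) {
  layer$conv1$params <- layer$params$conv1
  layer$conv2$params <- layer$params$conv2
  if (!is.null(layer$gate)) layer$gate$params <- layer$params$gate
  if (!is.null(layer$shortcut)) layer$shortcut$params <- layer$params$shortcut
  layer
}

resblock_forward <- function(layer, x, train) {
  layer <- sync_block_params(layer)
  f1 <- nn_forward(layer$conv1, x, train)
  r1 <- nn_forward(nn_relu(), f1$out, train)
  f2 <- nn_forward(layer$conv2, r1$out, train)
  h <- f2$out
  gc <- NULL
  gates <- NULL
  if (!is.null(layer$gate)) {
    fg <- nn_forward(layer$gate, h, train)
    h <- fg$out
    gc <- fg$cache
    gates <- fg$gates
  }
  sc <- NULL
  sx <- x
  if (!is.null(layer$shortcut)) {
    fs <- nn_forward(layer$shortcut, x, train)
    sx <- fs$out
    sc <- fs$cache
  }
  pre <- h + sx
  out <- pmax(pre, 0)
  dim(out) <- dim(pre)
  list(out = out, gates = gates,
       cache = if (train) list(c1 = f1$cache, r1 = r1$cache, c2 = f2$cache,
                               gate = gc, short = sc, pos = pre > 0))
}

resblock_backward <- function(layer, cache, dout) {
  layer <- sync_block_params(layer)
  dpre <- dout * cache$pos
  # shortcut path
  if (!is.null(layer$shortcut)) {
    bs <- nn_backward(layer$shortcut, cache$short, dpre)
    dx_short <- bs$dx
    g_short <- bs$grads
  } else {
    dx_short <- dpre
    g_short <- NULL
  }
  # main path
  dh <- dpre
  g_gate <- NULL
  if (!is.null(layer$gate)) {
    bg <- nn_backward(layer$gate, cache$gate, dh)
    dh <- bg$dx
    g_gate <- bg$grads
  }
  b2 <- nn_backward(layer$conv2, cache$c2, dh)
  br <- nn_backward(nn_relu(), cache$r1, b2$dx)
  b1 <- nn_backward(layer$conv1, cache$c1, br$dx)
  list(dx = b1$dx + dx_short,
       grads = list(conv1 = b1$grads, conv2 = b2$grads,
                    gate = g_gate, shortcut = g_short))
}

# Sequential containers --------------------------------------------------------

net_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  bn <- vector("list", length(layers))
  gates <- NULL
  for (i in seq_along(layers)) {
    f <- nn_forward(layers[[i]], x, train)
    x <- f$out
    caches[[i]] <- f$cache
    bn[i] <- list(f$bn_stats)
    if (!is.null(f$gates) && is.null(gates)) gates <- f$gates
  }
  list(out = x, caches = caches, gates = gates, bn = bn)
}

net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- nn_backward(layers[[i]], caches[[i]], dout)
    dout <- b$dx
    grads[i] <- list(b$grads) # keep NULL grads as placeholders
  }
  list(dx = dout, grads = grads)
}

net_params <- function(layers) lapply(layers, function(l) l$params)

net_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    if (!is.null(params[[i]])) layers[[i]]$params <- params[[i]]
  }
  layers
}

n_params <- function(params) {
  sum(rapply(params, length, how = "unlist"), 0)
}

# SGD with classical momentum over arbitrarily nested parameter lists.

sgd_state <- function(params) rapply(params, function(a) a * 0, how = "replace")

# One SGD step over a whole layer list, honouring per-layer `lr_mult`
# (used to let the few attention parameters move faster than the bulk
# convolutional weights).
net_update <- function(layers, grads, state, lr, momentum = 0.9,
                       weight_decay = 0) {
  for (i in seq_along(layers)) {
    if (is.null(layers[[i]]$params) || is.null(grads[[i]])) next
    mult <- if (is.null(layers[[i]]$lr_mult)) 1 else layers[[i]]$lr_mult
    wd <- if (layers[[i]]$type == "bnorm") 0 else weight_decay
    upd <- sgd_step(layers[[i]]$params, grads[[i]], state[[i]],
                    lr * mult, momentum, wd)
    layers[[i]]$params <- upd$params
    state[i] <- list(upd$state)
  }
  list(layers = layers, state = state)
}

sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                     weight_decay = 0) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      for (nm in seq_along(p)) {
        if (is.null(p[[nm]]) || is.null(g[[nm]])) next
        res <- walk(p[[nm]], g[[nm]], v[[nm]])
        p[[nm]] <- res$p
        v[[nm]] <- res$v
      }
      return(list(p = p, v = v))
    }
    v <- momentum * v + g + weight_decay * p
    list(p = p - lr * v, v = v)
  }
  res <- walk(params, grads, state)
  list(params = res$p, state = res$v)
}
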