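## Minimal feed-forward/convolutional network core with manual
## backpropagation. Layouts: image batches are (N, H, W, C) arrays, feature
## batches are (N, K) matrices. Convolutions are 3x3, stride 1, zero-padded
## ("same"), computed via im2col in sample chunks to bound transient memory.

layer_conv <- function(in_ch, out_ch) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch,
       W = matrix(stats::rnorm(9L * in_ch * out_ch, 0,
                               sqrt(2 / (9 * in_ch))), 9L * in_ch, out_ch),
       b = numeric(out_ch))
}

layer_fc <- function(in_dim, out_dim) {
  list(type = "fc", in_dim = in_dim, out_dim = out_dim,
       W = matrix(stats::rnorm(in_dim * out_dim, 0, sqrt(2 / in_dim)),
                  in_dim, out_dim),
       b = numeric(out_dim))
}

layer_bn <- function(dim, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", dim = dim, momentum = momentum, eps = eps,
       gamma = rep(1, dim), beta = numeric(dim),
       run_mean = numeric(dim), run_var = rep(1, dim))
}

layer_relu <- function() list(type = "relu")
layer_pool2 <- function() list(type = "pool2")
layer_gap <- function() list(type = "gap")

param_names <- function(layer) {
  switch(layer$type, conv = , fc = c("W", "b"), bn = c("gamma", "beta"),
         character(0))
}

## im2col for a (n, H, W, C) chunk with 3x3 kernel, pad 1.
im2col3 <- function(x) {
  d <- dim(x); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  xp <- array(0, dim = c(n, H + 2L, W + 2L, C))
  xp[, 2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, n * H * W, 9L * C)
  o <- 0L
  for (dh in 0:2) for (dw in 0:2) {
    sl <- xp[, (1L + dh):(H + dh), (1L + dw):(W + dw), , drop = FALSE]
    dim(sl) <- c(n * H * W, C)
    cols[, (o * C + 1L):((o + 1L) * C)] <- sl
    o <- o + 1L
  }
  cols
}

conv_chunks <- function(N, H, W, C) {
  per <- H * W * 9L * C
  size <- max(1L, floor(4e6 / per))
  split(seq_len(N), ceiling(seq_len(N) / size))
}

nn_forward_layer <- function(layer, x, train) {
  switch(layer$type,
    conv = {
      d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      y <- array(0, dim = c(N, H, W, layer$out_ch))
      for (idx in conv_chunks(N, H, W, C)) {
        cols <- im2col3(x[idx, , , , drop = FALSE])
        y2 <- cols %*% layer$W
        y2 <- sweep(y2, 2L, layer$b, "+")
        dim(y2) <- c(length(idx), H, W, layer$out_ch)
        y[idx, , , ] <- y2
      }
      list(out = y, cache = list(x = x))
    },
    fc = {
      y <- sweep(x %*% layer$W, 2L, layer$b, "+")
      list(out = y, cache = list(x = x))
    },
    bn = {
      if (train) {
        n <- nrow(x)
        mu <- colMeans(x)
        xc <- sweep(x, 2L, mu)
        v <- colMeans(xc^2)
        ivar <- 1 / sqrt(v + layer$eps)
        xhat <- sweep(xc, 2L, ivar, "*")
        y <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
        list(out = y,
             cache = list(xhat = xhat, ivar = ivar, n = n, mu = mu, v = v))
      } else {
        xhat <- sweep(sweep(x, 2L, layer$run_mean), 2L,
                      1 / sqrt(layer$run_var + layer$eps), "*")
        y <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
        list(out = y, cache = NULL)
      }
    },
    relu = {
      m <- x > 0
      x[!m] <- 0
      list(out = x, cache = list(mask = m))
    },
    pool2 = {
      d <- dim(x); H <- d[2]; W <- d[3]
      o1 <- seq(1L, H, 2L); e1 <- seq(2L, H, 2L)
      o2 <- seq(1L, W, 2L); e2 <- seq(2L, W, 2L)
      y <- (x[, o1, o2, , drop = FALSE] + x[, e1, o2, , drop = FALSE] +
            x[, o1, e2, , drop = FALSE] + x[, e1, e2, , drop = FALSE]) / 4
      list(out = y, cache = list(dim = d))
    },
    gap = {
      d <- dim(x); N <- d[1]; HW <- d[2] * d[3]; C <- d[4]
      xm <- x; dim(xm) <- c(N, HW, C)
      y <- matrix(0, N, C)
      for (ch in seq_len(C)) y[, ch] <- rowMeans(xm[, , ch, drop = FALSE])
      list(out = y, cache = list(dim = d))
    },
    stop("unknown layer type: ", layer$type))
}

nn_backward_layer <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      x <- cache$x
      d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      Fh <- layer$out_ch
      dW <- matrix(0, nrow(layer$W), Fh); db <- numeric(Fh)
      dx <- array(0, dim = d)
      for (idx in conv_chunks(N, H, W, C)) {
        n <- length(idx)
        cols <- im2col3(x[idx, , , , drop = FALSE])
        dy <- dout[idx, , , , drop = FALSE]
        dim(dy) <- c(n * H * W, Fh)
        dW <- dW + crossprod(cols, dy)
        db <- db + colSums(dy)
        dcols <- dy %*% t(layer$W)
        dxp <- array(0, dim = c(n, H + 2L, W + 2L, C))
        o <- 0L
        for (dh in 0:2) for (dw in 0:2) {
          blk <- dcols[, (o * C + 1L):((o + 1L) * C), drop = FALSE]
          dim(blk) <- c(n, H, W, C)
          dxp[, (1L + dh):(H + dh), (1L + dw):(W + dw), ] <-
            dxp[, (1L + dh):(H + dh), (1L + dw):(W + dw), , drop = FALSE] + blk
          o <- o + 1L
        }
        dx[idx, , , ] <- dxp[, 2:(H + 1L), 2:(W + 1L), , drop = FALSE]
      }
      list(grads = list(W = dW, b = db), dx = dx)
    },
    fc = {
      list(grads = list(W = crossprod(cache$x, dout), b = colSums(dout)),
           dx = dout %*% t(layer$W))
    },
    bn = {
      xhat <- cache$xhat; n <- cache$n
      dgamma <- colSums(dout * xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2L, layer$gamma, "*")
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- sweep(n * dxhat, 2L, s1) - sweep(xhat, 2L, s2, "*")
      dx <- sweep(dx, 2L, cache$ivar / n, "*")
      list(grads = list(gamma = dgamma, beta = dbeta), dx = dx)
    },
    relu = {
      dout[!cache$mask] <- 0
      list(grads = NULL, dx = dout)
    },
    pool2 = {
      d <- cache$dim
      dx <- array(0, dim = d)
      o1 <- seq(1L, d[2], 2L); e1 <- seq(2L, d[2], 2L)
      o2 <- seq(1L, d[3], 2L); e2 <- seq(2L, d[3], 2L)
      q <- dout / 4
      dx[, o1, o2, ] <- q; dx[, e1, o2, ] <- q
      dx[, o1, e2, ] <- q; dx[, e1, e2, ] <- q
      list(grads = NULL, dx = dx)
    },
    gap = {
      d <- cache$dim; HW <- d[2] * d[3]
      dx <- array(0, dim = d)
      for (ch in seq_len(d[4])) dx[, , , ch] <- dout[, ch] / HW
      list(grads = NULL, dx = dx)
    })
}

## Forward through a layer list; returns output and per-layer caches, and
## (train mode) updates batch-norm running statistics in the returned layers.
nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- nn_forward_layer(layers[[i]], x, train)
    x <- res$out
    caches[[i]] <- res$cache
    if (train && layers[[i]]$type == "bn") {
      mom <- layers[[i]]$momentum
      layers[[i]]$run_mean <- (1 - mom) * layers[[i]]$run_mean +
        mom * res$cache$mu
      layers[[i]]$run_var <- (1 - mom) * layers[[i]]$run_var +
        mom * res$cache$v
    }
  }
  list(out = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    res <- nn_backward_layer(layers[[i]], caches[[i]], dout)
    grads[i] <- list(res$grads)  # keep NULL slots for parameter-free layers
    dout <- res$dx
  }
  list(grads = grads, dx = dout)
}

## ---------------------------------------------------------------------------
## Adam with decoupled-from-architecture L2 weight decay on weight matrices.

adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- param_names(l)
    if (!length(nm)) return(NULL)
    st <- lapply(nm, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    stats::setNames(st, nm)
  })
}

adam_step <- function(layers, grads, state, t, lr,
                      weight_decay = 0, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(layers)) {
    nm <- param_names(layers[[i]])
    for (p in nm) {
      g <- grads[[i]][[p]]
      if (weight_decay > 0 && p == "W") g <- g + weight_decay * layers[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}
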