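# Low-level neural-network primitives: forward passes paired with manual
# backward passes. Matrices hold one token/feature vector per row; batches
# of images for the convolutional nets are (H, W, C, B) arrays. Correctness
# of every backward pass is guarded by the finite-difference gradient test.

nn_linear_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2L, b, "+")
  list(y = y, cache = list(x = x, W = W))
}

nn_linear_bwd <- function(dy, cache) {
  list(dx = dy %*% t(cache$W),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

nn_relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
nn_relu_bwd <- function(dy, cache) dy * cache

# row-wise layer normalization with learned gain/bias
nn_layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat * rep(g, each = nrow(x)), 2L, b, "+")
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

nn_layernorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$g
  d <- ncol(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  list(dx = dx,
       dg = colSums(dy * xhat),
       db = colSums(dy))
}

# numerically stable row-wise softmax
nn_softmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# backward of y = softmax(x) rows given dy
nn_softmax_bwd <- function(dy, y) {
  y * (dy - rowSums(dy * y))
}

# inverted dropout; draws from the current RNG stream
nn_dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  keep <- (stats::runif(length(x)) >= p) / (1 - p)
  dim(keep) <- dim(x)
  list(y = x * keep, cache = keep)
}

nn_dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# ---- 2-D convolution via im2col --------------------------------------------

# gather-index matrix for one padded image: rows = output positions
# (row-major over (i, j) column-major in R: i fastest), cols = (di, dj, c)
conv_im2col_idx <- function(hp, wp, cin, k, stride, hout, wout) {
  oi <- rep(seq_len(hout), times = wout)
  oj <- rep(seq_len(wout), each = hout)
  base_i <- (oi - 1L) * stride
  base_j <- (oj - 1L) * stride
  idx <- matrix(0L, nrow = hout * wout, ncol = k * k * cin)
  col <- 1L
  for (c in seq_len(cin)) {
    off_c <- (c - 1L) * hp * wp
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        idx[, col] <- (base_i + di) + (base_j + dj - 1L) * hp + off_c
        col <- col + 1L
      }
    }
  }
  idx
}

conv_pad <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# x: (H, W, Cin, B); W: (k*k*Cin) x Cout matrix; b: length Cout
conv2d_fwd <- function(x, W, b, k, stride = 1L, pad = 0L) {
  d <- dim(x)
  hp <- d[1] + 2L * pad; wp <- d[2] + 2L * pad
  hout <- (hp - k) %/% stride + 1L
  wout <- (wp - k) %/% stride + 1L
  xp <- conv_pad(x, pad)
  idx <- conv_im2col_idx(hp, wp, d[3], k, stride, hout, wout)
  per_img <- hp * wp * d[3]
  B <- d[4]
  npos <- nrow(idx)
  xcol <- matrix(0, nrow = npos * B, ncol = ncol(idx))
  xp_flat <- as.vector(xp)
  for (bb in seq_len(B)) {
    xcol[(bb - 1L) * npos + seq_len(npos), ] <- xp_flat[idx + (bb - 1L) * per_img]
  }
  y <- sweep(xcol %*% W, 2L, b, "+")
  yarr <- array(0, dim = c(hout, wout, length(b), B))
  for (bb in seq_len(B)) {
    yarr[, , , bb] <- array(y[(bb - 1L) * npos + seq_len(npos), ], dim = c(hout, wout, length(b)))
  }
  list(y = yarr,
       cache = list(xcol = xcol, W = W, idx = idx, per_img = per_img,
                    dpad = c(hp, wp, d[3], B), pad = pad, din = d,
                    npos = npos))
}

conv2d_bwd <- function(dy, cache) {
  dd <- dim(dy)
  B <- dd[4]; cout <- dd[3]
  npos <- cache$npos
  dymat <- matrix(0, nrow = npos * B, ncol = cout)
  for (bb in seq_len(B)) {
    dymat[(bb - 1L) * npos + seq_len(npos), ] <- matrix(dy[, , , bb], nrow = npos)
  }
  dW <- crossprod(cache$xcol, dymat)
  db <- colSums(dymat)
  dxcol <- dymat %*% t(cache$W)
  dp_flat <- numeric(prod(cache$dpad))
  idx <- cache$idx
  per_img <- cache$per_img
  for (bb in seq_len(B)) {
    off <- (bb - 1L) * per_img
    rows <- (bb - 1L) * npos + seq_len(npos)
    for (j in seq_len(ncol(idx))) {
      tgt <- idx[, j] + off
      dp_flat[tgt] <- dp_flat[tgt] + dxcol[rows, j]
    }
  }
  dp <- array(dp_flat, dim = cache$dpad)
  pad <- cache$pad; din <- cache$din
  dx <- if (pad > 0L) {
    dp[pad + seq_len(din[1]), pad + seq_len(din[2]), , , drop = FALSE]
  } else dp
  list(dx = dx, dW = dW, db = db)
}

# ---- parameter trees --------------------------------------------------------

# apply f elementwise over parallel nested lists of numeric arrays
tree_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(a)
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros_like <- function(p) tree_map(function(x) x * 0, p)

tree_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, tree_flatten), use.names = FALSE) else as.vector(p)
}

tree_unflatten <- function(skel, v) {
  pos <- 0L
  rebuild <- function(s) {
    if (is.list(s)) {
      out <- lapply(s, rebuild)
      names(out) <- names(s)
      out
    } else {
      n <- length(s)
      x <- v[pos + seq_len(n)]
      pos <<- pos + n
      if (!is.null(dim(s))) dim(x) <- dim(s)
      x
    }
  }
  rebuild(skel)
}

# SGD with classical momentum and L2 weight decay
sgd_step <- function(params, grads, state, lr, momentum = 0.9, weight_decay = 0) {
  if (is.null(state)) state <- tree_zeros_like(params)
  state <- tree_map(function(v, g, p) momentum * v + g + weight_decay * p,
                    state, grads, params)
  params <- tree_map(function(p, v) p - lr * v, params, state)
  list(params = params, state = state)
}

# Adam with L2 weight decay folded into the gradient
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  if (is.null(state)) {
    state <- list(m = tree_zeros_like(params), v = tree_zeros_like(params),
                  t = 0L)
  }
  state$t <- state$t + 1L
  g <- if (weight_decay > 0) {
    tree_map(function(gg, p) gg + weight_decay * p, grads, params)
  } else grads
  state$m <- tree_map(function(m, gg) beta1 * m + (1 - beta1) * gg, state$m, g)
  state$v <- tree_map(function(v, gg) beta2 * v + (1 - beta2) * gg^2, state$v, g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# dispatcher used by the training loops
optim_step <- function(optimizer, params, grads, state, lr, momentum = 0.9,
                       weight_decay = 0) {
  if (optimizer == "adam") {
    adam_step(params, grads, state, lr, weight_decay = weight_decay)
  } else {
    sgd_step(params, grads, state, lr, momentum = momentum,
             weight_decay = weight_decay)
  }
}

rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
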