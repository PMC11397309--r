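# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. These deliberately share no code with R/:
# they loop pixel by pixel and recompute everything from first principles.

rhu <- function(x) floor(x + 0.5)

# seeded random grayscale or RGB raster image
random_raster <- function(h, w, channels = 1L, levels = 256L, seed = 1L) {
  withr::with_seed(seed, {
    raster_image(array(sample.int(levels, h * w * channels, replace = TRUE) - 1L,
                       dim = c(h, w, channels)), levels = levels)
  })
}

# histogram equalization by direct CDF evaluation, one pixel at a time
oracle_equalize <- function(plane, L) {
  n <- length(plane)
  out <- plane
  for (i in seq_along(plane)) {
    cdf <- sum(plane <= plane[i]) / n
    out[i] <- rhu((L - 1) * cdf)
  }
  out
}

# contrast stretch by scalar arithmetic per pixel
oracle_stretch <- function(plane, r_min, r_max, L) {
  out <- plane
  for (i in seq_along(plane)) {
    r <- min(max(plane[i], r_min), r_max)
    out[i] <- rhu((r - r_min) / (r_max - r_min) * (L - 1))
  }
  out
}

# k x k median filter with replicate padding, sort-based, one pixel at a time
oracle_median <- function(plane, k) {
  h <- nrow(plane); w <- ncol(plane)
  r <- (k - 1) %/% 2
  out <- plane
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- numeric(0)
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      vals <- c(vals, plane[ii, jj])
    }
    out[i, j] <- sort(vals)[(k * k + 1) / 2]
  }
  out
}

# dense Gaussian convolution with replicate padding, scalar accumulation
oracle_gauss <- function(plane, sigma, L) {
  R <- ceiling(3 * sigma)
  kern <- matrix(0, 2 * R + 1, 2 * R + 1)
  for (x in -R:R) for (y in -R:R) {
    kern[x + R + 1, y + R + 1] <- exp(-(x^2 + y^2) / (2 * sigma^2))
  }
  kern <- kern / sum(kern)
  h <- nrow(plane); w <- ncol(plane)
  out <- plane
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -R:R) for (dj in -R:R) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      acc <- acc + kern[di + R + 1, dj + R + 1] * plane[ii, jj]
    }
    out[i, j] <- min(max(rhu(acc), 0), L - 1)
  }
  out
}

# confusion-matrix metrics by direct counting over prediction pairs
oracle_metrics <- function(y_true, y_pred, K) {
  conf <- matrix(0, K, K)
  for (i in seq_along(y_true)) {
    conf[y_true[i] + 1, y_pred[i] + 1] <- conf[y_true[i] + 1, y_pred[i] + 1] + 1
  }
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- conf[k, k]
    prec[k] <- if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else NA
    rec[k] <- if (sum(conf[k, ]) > 0) tp / sum(conf[k, ]) else NA
    f1[k] <- if (!is.na(prec[k]) && !is.na(rec[k]) && prec[k] + rec[k] > 0) {
      2 * prec[k] * rec[k] / (prec[k] + rec[k])
    } else if (!is.na(prec[k]) && !is.na(rec[k])) 0 else NA
  }
  list(confusion = conf, precision = prec, recall = rec, f1 = f1,
       accuracy = sum(diag(conf)) / length(y_true))
}

# tiny shared model configuration for network tests
tiny_cfg <- function(...) {
  attention_config(layers = 1L, heads = 1L, head_dim = 6L, ffn_hidden = 10L,
                   branches = 2L, image_size = 8L, patch = 4L, channels = 1L,
                   n_classes = 3L, dropout = 0, ...)
}

# numeric gradient of f at params by central differences on chosen indices
numeric_grad <- function(f, params, idx, eps = 1e-5) {
  flat <- leafpad:::tree_flatten(params)
  g <- numeric(length(idx))
  for (i in seq_along(idx)) {
    v <- flat; v[idx[i]] <- flat[idx[i]] + eps
    lp <- f(leafpad:::tree_unflatten(params, v))
    v[idx[i]] <- flat[idx[i]] - eps
    lm <- f(leafpad:::tree_unflatten(params, v))
    g[i] <- (lp - lm) / (2 * eps)
  }
  g
}
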