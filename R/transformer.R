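# Parallel-attention Transformer classifier with a reconstruction head.
#
# Architecture: an image is cut into p x p patches, each flattened and
# linearly embedded to d_model (= heads x head_dim), plus a learned
# positional embedding. Each of `layers` blocks runs N parallel multi-head
# attention branches on the same (layer-normalized) input; branch outputs
# are fused by weighted summation (softmax-normalized weights, learned by
# default or derived from history deltas in temporal mode), added back
# residually, then a 2-layer ReLU feed-forward net (pre-norm order).
# Classification mean-pools the final tokens into K logits; reconstruction
# maps final tokens back to patches. Heads *within* a branch are
# concatenated (8 x 64 = 512 under the default configuration); branches
# *across* are weighted-summed.

#' Attention / model configuration
#'
#' Defaults mirror the reference configuration: 12 layers, 8 heads of
#' dimension 64 (model width 512), feed-forward widths 2048 -> 512, ReLU,
#' 3 parallel branches fused by weighted summation, 64 x 64 RGB input cut
#' into 8 x 8 patches (64 tokens).
#'
#' @param layers encoder depth.
#' @param heads attention heads per branch.
#' @param head_dim per-head dimension; model width is \code{heads * head_dim}.
#' @param ffn_hidden feed-forward hidden width.
#' @param branches number of parallel attention branches N.
#' @param fusion \code{"weighted_sum"} (learned softmax weights) or
#'   \code{"temporal"} (weights from [temporal_weights()] over
#'   \code{fusion_deltas}).
#' @param attention_mode \code{"parallel"}, \code{"self"} (N = 1) or
#'   \code{"cross"} (2 branches, the second attending to the
#'   enhancement-stream tokens of the same image).
#' @param image_size input side I (square images).
#' @param patch patch side p; I must be divisible by p.
#' @param channels input channels (1 or 3).
#' @param n_classes number of classes K.
#' @param dropout dropout rate on attention and feed-forward outputs.
#' @param fusion_deltas N x 2 matrix of (time interval, data change) deltas
#'   for temporal fusion.
#' @param temporal_a,temporal_b nonnegative temporal weighting coefficients.
#' @param debug_checks assert row-stochastic attention weights during the
#'   forward pass.
#' @return list of class \code{attention_config}.
#' @export
attention_config <- function(layers = 12L, heads = 8L, head_dim = 64L,
                             ffn_hidden = 2048L, branches = 3L,
                             fusion = c("weighted_sum", "temporal"),
                             attention_mode = c("parallel", "self", "cross"),
                             image_size = 64L, patch = 8L, channels = 3L,
                             n_classes = 6L, dropout = 0.1,
                             fusion_deltas = NULL, temporal_a = 1,
                             temporal_b = 1, debug_checks = FALSE) {
  fusion <- match.arg(fusion)
  attention_mode <- match.arg(attention_mode)
  cfg <- list(layers = as.integer(layers), heads = as.integer(heads),
              head_dim = as.integer(head_dim),
              d_model = as.integer(heads * head_dim),
              ffn_hidden = as.integer(ffn_hidden),
              branches = as.integer(branches), fusion = fusion,
              attention_mode = attention_mode,
              image_size = as.integer(image_size), patch = as.integer(patch),
              channels = as.integer(channels), n_classes = as.integer(n_classes),
              dropout = dropout, fusion_deltas = fusion_deltas,
              temporal_a = temporal_a, temporal_b = temporal_b,
              debug_checks = debug_checks)
  class(cfg) <- "attention_config"
  set_attention_mode(cfg, attention_mode)
}

#' Switch the attention mode of a configuration
#'
#' \code{"self"} uses a single branch (a standard ViT-style encoder);
#' \code{"cross"} uses two branches where the second branch's keys and
#' values come from the enhancement-stream tokens of the same image;
#' \code{"parallel"} uses N branches fused by weighted summation.
#'
#' @param cfg [attention_config()].
#' @param mode one of \code{"self"}, \code{"cross"}, \code{"parallel"}.
#' @return updated configuration.
#' @export
set_attention_mode <- function(cfg, mode = c("parallel", "self", "cross")) {
  mode <- match.arg(mode)
  cfg$attention_mode <- mode
  cfg$n_branches <- switch(mode,
                           self = 1L,
                           cross = 2L,
                           parallel = cfg$branches)
  if (cfg$image_size %% cfg$patch != 0L) {
    stop("image_size must be divisible by patch", call. = FALSE)
  }
  cfg$n_tokens <- as.integer((cfg$image_size %/% cfg$patch)^2)
  cfg$patch_dim <- as.integer(cfg$patch^2 * cfg$channels)
  cfg
}

#' Cut an image into flattened patch vectors
#'
#' Cuts a square \code{I x I x C} image into \code{T = (I/p)^2} patches in
#' row-major patch order and flattens each to a length \code{p^2 C} vector
#' (identity projection; the model applies its learned embedding on top).
#'
#' @param x tensor or plain array \code{I x I x C} (a matrix is treated as
#'   single-channel).
#' @param p patch side; must divide I.
#' @return \code{T x (p^2 C)} matrix.
#' @export
patchify <- function(x, p) {
  x <- unclass(x)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  d <- dim(x)
  if (d[1] != d[2]) stop("patchify expects a square image", call. = FALSE)
  if (d[1] %% p != 0L) stop("image side must be divisible by patch size", call. = FALSE)
  G <- d[1] %/% p
  out <- matrix(0, nrow = G * G, ncol = p * p * d[3])
  for (gi in seq_len(G)) {
    rows <- (gi - 1L) * p + seq_len(p)
    for (gj in seq_len(G)) {
      cols <- (gj - 1L) * p + seq_len(p)
      out[(gi - 1L) * G + gj, ] <- as.vector(x[rows, cols, , drop = FALSE])
    }
  }
  out
}

#' Reassemble an image from flattened patch vectors
#'
#' Inverse of [patchify()].
#'
#' @param tokens \code{T x (p^2 C)} matrix.
#' @param p patch side.
#' @param channels channel count C.
#' @return \code{I x I x C} array.
#' @export
unpatchify <- function(tokens, p, channels = 1L) {
  G <- as.integer(sqrt(nrow(tokens)))
  if (G * G != nrow(tokens)) stop("token count must be a perfect square", call. = FALSE)
  I <- G * p
  out <- array(0, dim = c(I, I, channels))
  for (gi in seq_len(G)) {
    rows <- (gi - 1L) * p + seq_len(p)
    for (gj in seq_len(G)) {
      cols <- (gj - 1L) * p + seq_len(p)
      out[rows, cols, ] <- array(tokens[(gi - 1L) * G + gj, ], dim = c(p, p, channels))
    }
  }
  out
}

#' Scaled dot-product attention
#'
#' \code{softmax(Q K' / sqrt(d_k)) V}; every row of the attention-weight
#' matrix sums to 1.
#'
#' @param Q,K,V query/key/value matrices; Q and K share the key dimension
#'   d_k, K and V share their row count.
#' @param return_weights also return the attention-weight matrix.
#' @return output matrix, or list(output, weights).
#' @export
attention_head <- function(Q, K, V, return_weights = FALSE) {
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    stop("attention shapes are not conformable", call. = FALSE)
  }
  P <- nn_softmax(Q %*% t(K) / sqrt(ncol(Q)))
  out <- P %*% V
  if (return_weights) list(output = out, weights = P) else out
}

#' Weighted-sum fusion of parallel attention branches
#'
#' Elementwise convex combination \code{sum_i w_i * branch_i} of N
#' same-shaped branch outputs.
#'
#' @param branch_outputs list of N matrices of identical shape.
#' @param w length-N nonnegative weights summing to 1.
#' @return fused matrix.
#' @export
parallel_fuse <- function(branch_outputs, w) {
  N <- length(branch_outputs)
  if (length(w) != N) stop("one weight per branch required", call. = FALSE)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("fusion weights must be nonnegative and sum to 1", call. = FALSE)
  }
  d <- dim(branch_outputs[[1]])
  for (i in seq_len(N)) {
    if (!identical(dim(branch_outputs[[i]]), d)) {
      stop("branch outputs must share a shape", call. = FALSE)
    }
  }
  out <- branch_outputs[[1]] * w[1]
  if (N > 1) for (i in 2:N) out <- out + branch_outputs[[i]] * w[i]
  out
}

#' History-state fusion weights
#'
#' Weights past states by recency and similarity:
#' \code{w_j = softmax_j(-(a * dT_j + b * dD_j))}, so small time intervals
#' and small data changes are upweighted.
#'
#' @param deltas matrix (or list of pairs) with columns (time interval dT,
#'   data change dD), one row per history entry.
#' @param a,b nonnegative weighting coefficients.
#' @return normalized weight vector.
#' @export
temporal_weights <- function(deltas, a = 1, b = 1) {
  if (a < 0 || b < 0) stop("a and b must be nonnegative", call. = FALSE)
  if (is.list(deltas)) deltas <- do.call(rbind, deltas)
  deltas <- matrix(as.numeric(deltas), ncol = 2)
  if (nrow(deltas) < 1L) stop("at least one history entry required", call. = FALSE)
  s <- -(a * deltas[, 1] + b * deltas[, 2])
  e <- exp(s - max(s))
  e / sum(e)
}

# ---- parameter initialization ----------------------------------------------

init_branch <- function(d, sd) {
  list(Wq = rnorm_mat(d, d, sd), bq = numeric(d),
       Wk = rnorm_mat(d, d, sd), bk = numeric(d),
       Wv = rnorm_mat(d, d, sd), bv = numeric(d),
       Wo = rnorm_mat(d, d, sd), bo = numeric(d))
}

#' Initialize parallel-attention Transformer parameters
#'
#' @param cfg [attention_config()].
#' @param seed integer seed for the Gaussian initialization.
#' @param init_sd weight standard deviation.
#' @return nested parameter list.
#' @export
transformer_init <- function(cfg, seed = 0L, init_sd = 0.02) {
  d <- cfg$d_model
  with_seed(seed, {
    blocks <- lapply(seq_len(cfg$layers), function(l) {
      list(ln1 = list(g = rep(1, d), b = numeric(d)),
           branches = lapply(seq_len(cfg$n_branches), function(i) init_branch(d, init_sd)),
           fusion_logits = numeric(cfg$n_branches),
           ln2 = list(g = rep(1, d), b = numeric(d)),
           ffn = list(W1 = rnorm_mat(d, cfg$ffn_hidden, init_sd), b1 = numeric(cfg$ffn_hidden),
                      W2 = rnorm_mat(cfg$ffn_hidden, d, init_sd), b2 = numeric(d)))
    })
    list(embed = list(W = rnorm_mat(cfg$patch_dim, d, init_sd), b = numeric(d)),
         pos = rnorm_mat(cfg$n_tokens, d, init_sd / 2),
         blocks = blocks,
         lnf = list(g = rep(1, d), b = numeric(d)),
         head = list(W = rnorm_mat(d, cfg$n_classes, init_sd), b = numeric(cfg$n_classes)),
         recon = list(W = rnorm_mat(d, cfg$patch_dim, init_sd), b = numeric(cfg$patch_dim)))
  })
}

#' Count model parameters
#' @param params parameter tree from [transformer_init()].
#' @return scalar parameter count.
#' @export
n_params <- function(params) length(tree_flatten(params))

branch_fusion_weights <- function(cfg, block_params) {
  if (cfg$fusion == "temporal") {
    if (is.null(cfg$fusion_deltas)) stop("temporal fusion needs fusion_deltas", call. = FALSE)
    list(w = temporal_weights(cfg$fusion_deltas, cfg$temporal_a, cfg$temporal_b),
         learned = FALSE)
  } else {
    z <- block_params$fusion_logits
    e <- exp(z - max(z))
    list(w = e / sum(e), learned = TRUE)
  }
}

# ---- batched forward / backward --------------------------------------------

# Multi-head attention over the stacked token matrix `hq` (queries) and
# `hkv` (keys/values), both (B*T) x d, attention confined to each image's
# own T-row block. Returns projected output + cache for the backward pass.
mha_fwd <- function(hq, hkv, bp, cfg, B) {
  Tn <- cfg$n_tokens; dk <- cfg$head_dim; H <- cfg$heads
  Q <- sweep(hq %*% bp$Wq, 2L, bp$bq, "+")
  K <- sweep(hkv %*% bp$Wk, 2L, bp$bk, "+")
  V <- sweep(hkv %*% bp$Wv, 2L, bp$bv, "+")
  O <- matrix(0, nrow(Q), ncol(Q))
  Ps <- vector("list", B * H)
  scal <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * Tn + seq_len(Tn)
    for (h in seq_len(H)) {
      hc <- (h - 1L) * dk + seq_len(dk)
      P <- nn_softmax(tcrossprod(Q[rows, hc, drop = FALSE], K[rows, hc, drop = FALSE]) * scal)
      if (cfg$debug_checks) stopifnot(all(abs(rowSums(P) - 1) < 1e-9))
      Ps[[(b - 1L) * H + h]] <- P
      O[rows, hc] <- P %*% V[rows, hc, drop = FALSE]
    }
  }
  out <- sweep(O %*% bp$Wo, 2L, bp$bo, "+")
  list(out = out,
       cache = list(hq = hq, hkv = hkv, Q = Q, K = K, V = V, O = O, Ps = Ps,
                    bp = bp, B = B))
}

mha_bwd <- function(dout, cache, cfg) {
  Tn <- cfg$n_tokens; dk <- cfg$head_dim; H <- cfg$heads
  bp <- cache$bp; B <- cache$B
  scal <- 1 / sqrt(dk)
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(bp$Wo)
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- (b - 1L) * Tn + seq_len(Tn)
    for (h in seq_len(H)) {
      hc <- (h - 1L) * dk + seq_len(dk)
      P <- cache$Ps[[(b - 1L) * H + h]]
      dOb <- dO[rows, hc, drop = FALSE]
      dV[rows, hc] <- dV[rows, hc] + crossprod(P, dOb)
      dP <- tcrossprod(dOb, cache$V[rows, hc, drop = FALSE])
      dS <- nn_softmax_bwd(dP, P) * scal
      dQ[rows, hc] <- dQ[rows, hc] + dS %*% cache$K[rows, hc, drop = FALSE]
      dK[rows, hc] <- dK[rows, hc] + crossprod(dS, cache$Q[rows, hc, drop = FALSE])
    }
  }
  grads <- list(Wq = crossprod(cache$hq, dQ), bq = colSums(dQ),
                Wk = crossprod(cache$hkv, dK), bk = colSums(dK),
                Wv = crossprod(cache$hkv, dV), bv = colSums(dV),
                Wo = dWo, bo = dbo)
  list(dhq = dQ %*% t(bp$Wq),
       dhkv = dK %*% t(bp$Wk) + dV %*% t(bp$Wv),
       grads = grads)
}

#' Batched Transformer forward pass
#'
#' @param x4 \code{(I, I, C, B)} array of tensor-image values.
#' @param cfg [attention_config()].
#' @param params parameters from [transformer_init()].
#' @param training apply dropout (consumes the current RNG stream).
#' @param enh4 enhancement-stream images (same shape as `x4`); required for
#'   cross attention mode.
#' @return list with \code{logits} (B x K), \code{recon} (same shape as
#'   `x4`) and a \code{cache} for [transformer_bwd()].
#' @export
transformer_fwd <- function(x4, cfg, params, training = FALSE, enh4 = NULL) {
  d <- dim(x4)
  B <- d[4]; Tn <- cfg$n_tokens
  Xall <- matrix(0, nrow = B * Tn, ncol = cfg$patch_dim)
  for (b in seq_len(B)) {
    Xall[(b - 1L) * Tn + seq_len(Tn), ] <- patchify(x4[, , , b, drop = TRUE], cfg$patch)
  }
  emb <- nn_linear_fwd(Xall, params$embed$W, params$embed$b)
  posrep <- params$pos[rep(seq_len(Tn), times = B), , drop = FALSE]
  x <- emb$y + posrep
  cross <- cfg$attention_mode == "cross"
  enh_tokens <- NULL; Xenh <- NULL
  if (cross) {
    if (is.null(enh4)) stop("cross attention mode requires enh4", call. = FALSE)
    Xenh <- matrix(0, nrow = B * Tn, ncol = cfg$patch_dim)
    for (b in seq_len(B)) {
      Xenh[(b - 1L) * Tn + seq_len(Tn), ] <- patchify(enh4[, , , b, drop = TRUE], cfg$patch)
    }
    enh_tokens <- sweep(Xenh %*% params$embed$W, 2L, params$embed$b, "+") + posrep
  }
  bcaches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    bp <- params$blocks[[l]]
    ln1 <- nn_layernorm_fwd(x, bp$ln1$g, bp$ln1$b)
    fw <- branch_fusion_weights(cfg, bp)
    mhas <- vector("list", cfg$n_branches)
    outs <- vector("list", cfg$n_branches)
    for (i in seq_len(cfg$n_branches)) {
      hkv <- if (cross && i == 2L) enh_tokens else ln1$y
      mhas[[i]] <- mha_fwd(ln1$y, hkv, bp$branches[[i]], cfg, B)
      outs[[i]] <- mhas[[i]]$out
    }
    fused <- parallel_fuse(outs, fw$w)
    drop1 <- nn_dropout_fwd(fused, cfg$dropout, training)
    x2 <- x + drop1$y
    ln2 <- nn_layernorm_fwd(x2, bp$ln2$g, bp$ln2$b)
    ff1 <- nn_linear_fwd(ln2$y, bp$ffn$W1, bp$ffn$b1)
    act <- nn_relu_fwd(ff1$y)
    ff2 <- nn_linear_fwd(act$y, bp$ffn$W2, bp$ffn$b2)
    drop2 <- nn_dropout_fwd(ff2$y, cfg$dropout, training)
    xout <- x2 + drop2$y
    bcaches[[l]] <- list(ln1 = ln1, mhas = mhas, outs = outs, fw = fw,
                         drop1 = drop1, ln2 = ln2, ff1 = ff1, act = act,
                         ff2 = ff2, drop2 = drop2)
    x <- xout
  }
  lnf <- nn_layernorm_fwd(x, params$lnf$g, params$lnf$b)
  pooled <- matrix(0, B, cfg$d_model)
  for (b in seq_len(B)) {
    pooled[b, ] <- colMeans(lnf$y[(b - 1L) * Tn + seq_len(Tn), , drop = FALSE])
  }
  headf <- nn_linear_fwd(pooled, params$head$W, params$head$b)
  reconf <- nn_linear_fwd(lnf$y, params$recon$W, params$recon$b)
  recon <- array(0, dim = d)
  for (b in seq_len(B)) {
    recon[, , , b] <- unpatchify(reconf$y[(b - 1L) * Tn + seq_len(Tn), , drop = FALSE],
                                 cfg$patch, cfg$channels)
  }
  list(logits = headf$y, recon = recon,
       cache = list(cfg = cfg, params = params, B = B, d = d,
                    emb = emb, Xall = Xall, Xenh = Xenh, cross = cross,
                    bcaches = bcaches, lnf = lnf, pooled = pooled,
                    headf = headf, reconf = reconf))
}

#' Backward pass of [transformer_fwd()]
#'
#' @param dlogits gradient w.r.t. logits (B x K).
#' @param drecon gradient w.r.t. the reconstruction (same shape as the
#'   input), or NULL for zero.
#' @param cache cache returned by the forward pass.
#' @return parameter-gradient tree shaped like the parameter list.
#' @export
transformer_bwd <- function(dlogits, drecon, cache) {
  cfg <- cache$cfg; params <- cache$params
  B <- cache$B; Tn <- cfg$n_tokens
  headb <- nn_linear_bwd(dlogits, cache$headf$cache)
  dlnf_y <- matrix(0, nrow = B * Tn, ncol = cfg$d_model)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * Tn + seq_len(Tn)
    dlnf_y[rows, ] <- matrix(headb$dx[b, ] / Tn, nrow = Tn, ncol = cfg$d_model, byrow = TRUE)
  }
  grecon <- list(W = matrix(0, cfg$d_model, cfg$patch_dim), b = numeric(cfg$patch_dim))
  if (!is.null(drecon)) {
    dR <- matrix(0, nrow = B * Tn, ncol = cfg$patch_dim)
    for (b in seq_len(B)) {
      dR[(b - 1L) * Tn + seq_len(Tn), ] <- patchify(drecon[, , , b, drop = TRUE], cfg$patch)
    }
    reconb <- nn_linear_bwd(dR, cache$reconf$cache)
    dlnf_y <- dlnf_y + reconb$dx
    grecon <- list(W = reconb$dW, b = reconb$db)
  }
  lnfb <- nn_layernorm_bwd(dlnf_y, cache$lnf$cache)
  dx <- lnfb$dx
  gblocks <- vector("list", cfg$layers)
  denh_tokens <- if (cache$cross) matrix(0, nrow = B * Tn, ncol = cfg$d_model) else NULL
  for (l in rev(seq_len(cfg$layers))) {
    bc <- cache$bcaches[[l]]
    bp <- params$blocks[[l]]
    dff_out <- nn_dropout_bwd(dx, bc$drop2$cache)
    ff2b <- nn_linear_bwd(dff_out, bc$ff2$cache)
    actb <- nn_relu_bwd(ff2b$dx, bc$act$cache)
    ff1b <- nn_linear_bwd(actb, bc$ff1$cache)
    ln2b <- nn_layernorm_bwd(ff1b$dx, bc$ln2$cache)
    dx2 <- dx + ln2b$dx
    dfused <- nn_dropout_bwd(dx2, bc$drop1$cache)
    w <- bc$fw$w
    dfl <- numeric(cfg$n_branches)
    dh <- matrix(0, nrow = B * Tn, ncol = cfg$d_model)
    gbranches <- vector("list", cfg$n_branches)
    for (i in seq_len(cfg$n_branches)) {
      mb <- mha_bwd(dfused * w[i], bc$mhas[[i]]$cache, cfg)
      gbranches[[i]] <- mb$grads
      dh <- dh + mb$dhq
      if (cache$cross && i == 2L) {
        denh_tokens <- denh_tokens + mb$dhkv
      } else {
        dh <- dh + mb$dhkv
      }
      if (bc$fw$learned) dfl[i] <- sum(dfused * bc$outs[[i]])
    }
    if (bc$fw$learned) {
      # softmax backward for the fusion logits
      dfl <- w * (dfl - sum(dfl * w))
    }
    ln1b <- nn_layernorm_bwd(dh, bc$ln1$cache)
    dx <- dx2 + ln1b$dx
    gblocks[[l]] <- list(ln1 = list(g = ln1b$dg, b = ln1b$db),
                         branches = gbranches,
                         fusion_logits = dfl,
                         ln2 = list(g = ln2b$dg, b = ln2b$db),
                         ffn = list(W1 = ff1b$dW, b1 = ff1b$db,
                                    W2 = ff2b$dW, b2 = ff2b$db))
  }
  dtokens <- dx
  embb <- nn_linear_bwd(dtokens, cache$emb$cache)
  gW <- embb$dW; gb <- embb$db
  dpos <- matrix(0, Tn, cfg$d_model)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * Tn + seq_len(Tn)
    dpos <- dpos + dtokens[rows, , drop = FALSE]
    if (cache$cross) dpos <- dpos + denh_tokens[rows, , drop = FALSE]
  }
  if (cache$cross) {
    gW <- gW + crossprod(cache$Xenh, denh_tokens)
    gb <- gb + colSums(denh_tokens)
  }
  list(embed = list(W = gW, b = gb),
       pos = dpos,
       blocks = gblocks,
       lnf = list(g = lnfb$dg, b = lnfb$db),
       head = list(W = headb$dW, b = headb$db),
       recon = grecon)
}

#' Single-image classifier forward pass
#'
#' Convenience wrapper around [transformer_fwd()]: patchifies one image,
#' runs the encoder and returns class logits plus the reconstruction.
#'
#' @param img tensor image (\code{I x I x C}) from [to_tensor()].
#' @param cfg [attention_config()].
#' @param params parameters from [transformer_init()].
#' @param enh optional enhancement-stream tensor image (cross mode).
#' @return list(logits, reconstruction).
#' @export
forward_classifier <- function(img, cfg, params, enh = NULL) {
  x4 <- array(unclass(img), dim = c(dim(img), 1L))
  enh4 <- if (!is.null(enh)) array(unclass(enh), dim = c(dim(enh), 1L)) else NULL
  fw <- transformer_fwd(x4, cfg, params, training = FALSE, enh4 = enh4)
  recon <- fw$recon[, , , 1L, drop = FALSE]
  dim(recon) <- dim(recon)[1:3]
  list(logits = as.vector(fw$logits), reconstruction = recon)
}

#' Apply one parallel-attention encoder block to a token sequence
#'
#' Exposes a single block (N parallel multi-head attention branches fused
#' by weighted summation, residual, layer norms, feed-forward) on a plain
#' \code{T x d_model} token matrix.
#'
#' @param seq token matrix (T x d_model).
#' @param cfg [attention_config()].
#' @param block_params one element of the \code{blocks} list from
#'   [transformer_init()].
#' @return list(y = output tokens, concat_width = width of the
#'   concatenated-heads matrix before the output projection).
#' @export
multi_head_block <- function(seq, cfg, block_params) {
  if (ncol(seq) != cfg$d_model) stop("token width must equal d_model", call. = FALSE)
  cfg2 <- cfg
  cfg2$n_tokens <- nrow(seq)
  ln1 <- nn_layernorm_fwd(seq, block_params$ln1$g, block_params$ln1$b)
  fw <- branch_fusion_weights(cfg2, block_params)
  outs <- lapply(seq_len(cfg2$n_branches), function(i) {
    mha_fwd(ln1$y, ln1$y, block_params$branches[[i]], cfg2, 1L)$out
  })
  x2 <- seq + parallel_fuse(outs, fw$w)
  ln2 <- nn_layernorm_fwd(x2, block_params$ln2$g, block_params$ln2$b)
  h <- pmax(sweep(ln2$y %*% block_params$ffn$W1, 2L, block_params$ffn$b1, "+"), 0)
  y <- x2 + sweep(h %*% block_params$ffn$W2, 2L, block_params$ffn$b2, "+")
  list(y = y, concat_width = cfg$heads * cfg$head_dim)
}
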