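test_that("patchify produces (I/p)^2 tokens and roundtrips with unpatchify", {
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  tk <- patchify(x, 4)
  expect_equal(dim(tk), c(16L, 48L))
  expect_equal(unpatchify(tk, 4, 3), x)
  # single-patch case
  tk1 <- patchify(x, 16)
  expect_equal(nrow(tk1), 1L)
  # 32 / 8 gives 16 tokens
  x32 <- array(0, dim = c(32, 32, 1))
  expect_equal(nrow(patchify(x32, 8)), 16L)
  expect_error(patchify(x, 5), "divisible")
  expect_error(patchify(array(0, dim = c(4, 6, 1)), 2), "square")
})

test_that("scaled dot-product attention matches hand-evaluated cases", {
  # sequence length 1: softmax of a scalar is 1, output = V
  Q <- matrix(1.3, 1, 2); K <- matrix(-0.2, 1, 2); V <- matrix(c(3, 7), 1, 2)
  expect_equal(attention_head(Q, K, V), V)
  # d_k = 1, Q = K = [1; 0], V = [1; 2]: first row = softmax(c(1,0)) . V
  Q <- matrix(c(1, 0), 2, 1); V <- matrix(c(1, 2), 2, 1)
  out <- attention_head(Q, Q, V, return_weights = TRUE)
  w <- exp(c(1, 0)) / sum(exp(c(1, 0)))
  expect_equal(out$output[1, 1], sum(w * c(1, 2)), tolerance = 1e-12)
  expect_equal(out$output[1, 1], 1.2689, tolerance = 1e-4)
  expect_equal(rowSums(out$weights), c(1, 1))
  expect_error(attention_head(matrix(0, 2, 3), matrix(0, 2, 2), V), "conformable")
})

test_that("attention rows are stochastic throughout a forward pass", {
  cfg <- tiny_cfg(debug_checks = TRUE)   # asserts row sums internally
  params <- transformer_init(cfg, seed = 1)
  x4 <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 1, 2))
  expect_no_error(transformer_fwd(x4, cfg, params))
  # and explicitly on a standalone head with random shapes
  withr::with_seed(2, {
    for (rep in 1:5) {
      n <- sample(2:6, 1); dk <- sample(1:4, 1)
      out <- attention_head(matrix(rnorm(n * dk), n), matrix(rnorm(n * dk), n),
                            matrix(rnorm(n * 2), n), return_weights = TRUE)
      expect_equal(rowSums(out$weights), rep(1, n), tolerance = 1e-12)
    }
  })
})

test_that("parallel fusion is a convex combination with identity edge cases", {
  a <- matrix(1, 3, 4); b <- matrix(2, 3, 4)
  expect_equal(parallel_fuse(list(a), 1), a)
  expect_equal(parallel_fuse(list(a, a), c(0.4, 0.6)), a)
  expect_true(all(parallel_fuse(list(a, b), c(0.3, 0.7)) == 1.7))
  expect_error(parallel_fuse(list(a, b), c(0.5, 0.6)), "sum to 1")
  expect_error(parallel_fuse(list(a, matrix(0, 2, 2)), c(0.5, 0.5)), "share a shape")
})

test_that("temporal weights softmax recency/similarity deltas", {
  expect_equal(temporal_weights(matrix(c(3, 5), 1)), 1)
  expect_equal(temporal_weights(rbind(c(2, 2), c(2, 2), c(2, 2))),
               rep(1 / 3, 3))
  w <- temporal_weights(rbind(c(1, 0), c(2, 0)), a = 1, b = 0)
  expect_equal(w, c(exp(-1), exp(-2)) / (exp(-1) + exp(-2)), tolerance = 1e-12)
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_error(temporal_weights(matrix(numeric(0), 0, 2)), "at least one")
  expect_error(temporal_weights(matrix(1, 1, 2), a = -1), "nonnegative")
})

test_that("multi_head_block keeps shape and concatenated width is heads x head_dim", {
  cfg <- attention_config(layers = 1, heads = 8, head_dim = 64, ffn_hidden = 128,
                          branches = 2, image_size = 16, patch = 8, channels = 1,
                          n_classes = 2, dropout = 0)
  params <- transformer_init(cfg, seed = 2)
  seq <- matrix(rnorm(4 * 512), 4, 512)
  out <- multi_head_block(seq, cfg, params$blocks[[1]])
  expect_equal(out$concat_width, 512L)
  expect_equal(dim(out$y), dim(seq))
  # zeroed attention output projections leave only the FFN path
  bp <- params$blocks[[1]]
  for (i in seq_along(bp$branches)) {
    bp$branches[[i]]$Wo[] <- 0; bp$branches[[i]]$bo[] <- 0
  }
  out0 <- multi_head_block(seq, cfg, bp)
  ln2 <- leafpad:::nn_layernorm_fwd(seq, bp$ln2$g, bp$ln2$b)
  h <- pmax(sweep(ln2$y %*% bp$ffn$W1, 2, bp$ffn$b1, "+"), 0)
  expected <- seq + sweep(h %*% bp$ffn$W2, 2, bp$ffn$b2, "+")
  expect_equal(out0$y, expected, tolerance = 1e-12)
})

test_that("classifier forward produces K logits and input-shaped reconstruction", {
  cfg <- tiny_cfg()
  params <- transformer_init(cfg, seed = 3)
  img <- array(runif(64, -1, 1), dim = c(8, 8, 1))
  out <- forward_classifier(img, cfg, params)
  expect_length(out$logits, 3L)
  expect_equal(dim(out$reconstruction), dim(img))
})

test_that("attention modes configure branch counts and parameters monotonically", {
  base <- attention_config(layers = 2, heads = 2, head_dim = 8, ffn_hidden = 32,
                           branches = 3, image_size = 8, patch = 4, channels = 1,
                           n_classes = 2, dropout = 0)
  modes <- c("self", "cross", "parallel")
  counts <- vapply(modes, function(md) {
    cfg <- set_attention_mode(base, md)
    n_params(transformer_init(cfg, seed = 1))
  }, numeric(1))
  expect_equal(set_attention_mode(base, "self")$n_branches, 1L)
  expect_equal(set_attention_mode(base, "cross")$n_branches, 2L)
  expect_equal(set_attention_mode(base, "parallel")$n_branches, 3L)
  expect_lt(counts["self"], counts["cross"])
  expect_lt(counts["cross"], counts["parallel"])
  expect_error(set_attention_mode(base, "banana"))
})

test_that("parallel mode with one branch equals self mode exactly", {
  base <- attention_config(layers = 1, heads = 2, head_dim = 4, ffn_hidden = 16,
                           branches = 1, image_size = 8, patch = 4, channels = 1,
                           n_classes = 2, dropout = 0)
  cfg_par <- set_attention_mode(base, "parallel")   # N = branches = 1
  cfg_self <- set_attention_mode(base, "self")
  p <- transformer_init(cfg_par, seed = 5)
  x4 <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 1, 2))
  out_par <- transformer_fwd(x4, cfg_par, p)
  out_self <- transformer_fwd(x4, cfg_self, p)
  expect_equal(out_par$logits, out_self$logits, tolerance = 1e-14)
  expect_equal(out_par$recon, out_self$recon, tolerance = 1e-14)
})

test_that("permuting patch tokens has no effect beyond the positional term", {
  # with the positional embedding zeroed, mean-pooled logits are invariant
  # to patch order (no hidden order dependence in the blocks)
  cfg <- tiny_cfg()
  params <- transformer_init(cfg, seed = 6)
  params$pos[] <- 0
  img <- array(runif(64, -1, 1), dim = c(8, 8, 1))
  perm_img <- img
  # swapping two spatial patch blocks permutes token order
  perm_img[1:4, 1:4, ] <- img[1:4, 5:8, ]
  perm_img[1:4, 5:8, ] <- img[1:4, 1:4, ]
  out1 <- forward_classifier(img, cfg, params)
  out2 <- forward_classifier(perm_img, cfg, params)
  expect_equal(out1$logits, out2$logits, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on tiny configurations", {
  # 2-token sequence exercised through a 1-layer 1-head block via the image
  # path (2x1 patch grid is not square, so use 4 tokens for the full model
  # and 2 tokens through multi_head_block's internals)
  cfg <- tiny_cfg()
  params <- transformer_init(cfg, seed = 3)
  withr::with_seed(10, {
    x4 <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 1, 2))
  })
  lab <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  loss_fn <- function(p) {
    fw <- transformer_fwd(x4, cfg, p)
    parallel_loss(fw$logits, lab, fw$recon, x4, NULL,
                  loss_weights(1, 0.5, 0))$total
  }
  fw <- transformer_fwd(x4, cfg, params)
  ls <- parallel_loss(fw$logits, lab, fw$recon, x4, NULL, loss_weights(1, 0.5, 0))
  gr <- transformer_bwd(ls$dlogits, ls$drecon, fw$cache)
  gflat <- leafpad:::tree_flatten(gr)
  idx <- withr::with_seed(11, sample(length(gflat), 100))
  num <- numeric_grad(loss_fn, params, idx)
  rel <- abs(num - gflat[idx]) / pmax(abs(num) + abs(gflat[idx]), 1e-5)
  expect_lt(max(rel), 1e-4)
})

test_that("cross-attention gradients flow through the enhancement stream", {
  cfg <- set_attention_mode(tiny_cfg(), "cross")
  params <- transformer_init(cfg, seed = 4)
  withr::with_seed(12, {
    x4 <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 1, 2))
    enh4 <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 1, 2))
  })
  lab <- matrix(c(1, 0, 0, 0, 0, 1), 2, 3, byrow = TRUE)
  loss_fn <- function(p) {
    fw <- transformer_fwd(x4, cfg, p, enh4 = enh4)
    parallel_loss(fw$logits, lab, fw$recon, x4, NULL,
                  loss_weights(1, 0.5, 0))$total
  }
  fw <- transformer_fwd(x4, cfg, params, enh4 = enh4)
  ls <- parallel_loss(fw$logits, lab, fw$recon, x4, NULL, loss_weights(1, 0.5, 0))
  gr <- transformer_bwd(ls$dlogits, ls$drecon, fw$cache)
  gflat <- leafpad:::tree_flatten(gr)
  idx <- withr::with_seed(13, sample(length(gflat), 60))
  num <- numeric_grad(loss_fn, params, idx)
  rel <- abs(num - gflat[idx]) / pmax(abs(num) + abs(gflat[idx]), 1e-5)
  expect_lt(max(rel), 1e-4)
})
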