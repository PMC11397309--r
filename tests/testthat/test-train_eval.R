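test_that("the composite loss is the stated weighted sum with exact linearity", {
  withr::with_seed(1, {
    logits <- matrix(rnorm(6), 2, 3)
    lab <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
    recon <- array(rnorm(8), dim = c(2, 2, 1, 2))
    input <- array(rnorm(8), dim = c(2, 2, 1, 2))
    score <- rnorm(2)
  })
  # lambda = (1, 0, 0): total is the classification loss alone
  only_cls <- parallel_loss(logits, lab, recon, input, score,
                            loss_weights(1, 0, 0))
  expect_equal(only_cls$total, unname(only_cls$components["cls"]))
  # perfect reconstruction: recon component is zero
  perfect <- parallel_loss(logits, lab, input, input, score, loss_weights())
  expect_equal(unname(perfect$components["recon"]), 0)
  # linearity in each lambda at fixed components
  base <- parallel_loss(logits, lab, recon, input, score, loss_weights(1, 1, 1))
  comp <- base$components
  for (rep in 1:10) {
    w <- withr::with_seed(rep, runif(3, 0, 2))
    tot <- parallel_loss(logits, lab, recon, input, score,
                         loss_weights(w[1], w[2], w[3]))$total
    expect_equal(tot, sum(w * comp), tolerance = 1e-12)
  }
  # scalar component check: components (1, 2, 3), weights (1, 0.5, 0.1) -> 2.3
  expect_equal(sum(c(1, 0.5, 0.1) * c(1, 2, 3)), 2.3)
  expect_error(loss_weights(-1, 0, 0), "nonnegative")
  expect_error(loss_weights(0, 0, 0), "positive")
})

test_that("focal loss reduces to cross-entropy at gamma 0 and scores its formula", {
  withr::with_seed(2, {
    logits <- matrix(rnorm(12), 4, 3)
    lab <- diag(3)[sample(1:3, 4, replace = TRUE), ]
  })
  f0 <- loss_mode("focal", gamma = 0)(logits, lab)
  ce <- loss_mode("cross_entropy")(logits, lab)
  expect_equal(f0$total, ce$total, tolerance = 1e-9)
  expect_equal(f0$dlogits, ce$dlogits, tolerance = 1e-10)
  # p_true = 0.5, gamma = 2: 0.25 * log 2
  l_half <- matrix(c(0, 0), 1, 2)   # softmax = (0.5, 0.5)
  fl <- leafpad:::focal_loss(l_half, matrix(c(1, 0), 1, 2), gamma = 2)
  expect_equal(fl$loss, 0.25 * log(2), tolerance = 1e-12)
  expect_equal(fl$loss, 0.1733, tolerance = 1e-4)
  # perfect prediction: zero loss
  sure <- matrix(c(100, 0), 1, 2)
  expect_equal(leafpad:::focal_loss(sure, matrix(c(1, 0), 1, 2), 2)$loss, 0,
               tolerance = 1e-10)
  expect_error(loss_mode("focal", gamma = -1), "nonnegative")
})

test_that("the learning-rate schedule decays 10% every 10 epochs from 0.001", {
  expect_equal(lr_at_epoch(0), 0.001)
  expect_equal(lr_at_epoch(9), 0.001)
  expect_equal(lr_at_epoch(10), 0.0009)
  expect_equal(lr_at_epoch(25), 0.00081)
  expect_equal(lr_at_epoch(100), 0.001 * 0.9^10)
  expect_error(lr_at_epoch(-1), "nonnegative")
})

test_that("k-fold plans partition with near-equal, stratified folds", {
  fp <- kfold_plan(10, 5, seed = 1)
  expect_equal(unname(table(fp$assignments)), rep(2L, 5), ignore_attr = TRUE)
  fp11 <- kfold_plan(11, 5, seed = 1)
  expect_equal(sort(unname(table(fp11$assignments)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L), ignore_attr = TRUE)
  # union of validation folds is the full index set
  expect_setequal(unlist(lapply(1:5, function(f) which(fp11$assignments == f))),
                  1:11)
  # stratified: per-class proportions within one record per fold
  labs <- rep(0:2, times = c(20, 15, 10))
  fps <- kfold_plan(45, 5, seed = 2, stratify_labels = labs)
  expect_equal(unname(table(fps$assignments)), rep(9L, 5), ignore_attr = TRUE)
  for (f in 1:5) {
    sel <- labs[fps$assignments == f]
    expect_lte(abs(sum(sel == 0) - 4), 1)
    expect_lte(abs(sum(sel == 1) - 3), 1)
  }
  expect_error(kfold_plan(3, 5), "n >= k")
})

test_that("metrics match hand-counted confusion arithmetic on random predictions", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      K <- sample(2:6, 1)
      n <- sample(20:80, 1)
      y_true <- sample(0:(K - 1), n, replace = TRUE)
      y_pred <- sample(0:(K - 1), n, replace = TRUE)
      mr <- metrics_report(y_true, y_pred, n_classes = K)
      or <- oracle_metrics(y_true, y_pred, K)
      expect_equal(unclass(mr$confusion), or$confusion, ignore_attr = TRUE)
      expect_equal(mr$accuracy, or$accuracy)
      expect_equal(unname(mr$precision), or$precision)
      expect_equal(unname(mr$recall), or$recall)
      expect_equal(unname(mr$f1), or$f1)
      expect_equal(sum(mr$confusion), n)
    }
  })
})

test_that("metric edge cases behave as documented", {
  # all-correct: every metric is 1
  mr <- metrics_report(c(0, 1, 2), c(0, 1, 2), n_classes = 3)
  expect_equal(mr$accuracy, 1)
  expect_equal(unname(mr$f1), rep(1, 3))
  expect_equal(mr$macro_f1, 1)
  # the printed binary example: [[8,2],[1,9]] -> accuracy 0.85
  y_true <- c(rep(0, 10), rep(1, 10))
  y_pred <- c(rep(0, 8), rep(1, 2), rep(1, 9), rep(0, 1))
  mr2 <- metrics_report(y_true, y_pred, n_classes = 2)
  expect_equal(mr2$accuracy, 0.85)
  # per-class P = R = v implies macro-F1 = v (harmonic mean of equals)
  y_sym <- c(rep(0, 10), rep(1, 10))
  p_sym <- c(rep(0, 8), rep(1, 2), rep(0, 2), rep(1, 8))
  mr_sym <- metrics_report(y_sym, p_sym, n_classes = 2)
  expect_equal(unname(mr_sym$precision), unname(mr_sym$recall))
  expect_equal(mr_sym$macro_f1, 0.8)
  # class absent from truth and prediction is excluded from macros
  mr3 <- metrics_report(c(0, 0, 1), c(0, 0, 1), n_classes = 3)
  expect_true(is.na(mr3$precision[3]))
  expect_equal(mr3$macro_f1, 1)
})

test_that("ROC curves are monotone with AUC in [0, 1] matching pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(4, {
    for (rep in 1:5) {
      n <- 60
      truth <- sample(0:1, n, replace = TRUE)
      score <- rnorm(n) + truth
      mr <- metrics_report(truth, truth,
                           scores = cbind(-score, score), n_classes = 2)
      rc <- mr$roc[[2]]
      expect_true(all(diff(rc$fpr) >= 0))
      expect_true(all(diff(rc$tpr) >= 0))
      expect_gte(mr$auc[2], 0); expect_lte(mr$auc[2], 1)
      ref <- suppressMessages(pROC::auc(truth, score))
      expect_equal(unname(mr$auc[2]), as.numeric(ref), tolerance = 1e-10)
    }
  })
})

test_that("grid search is exhaustive with deterministic tie-breaks", {
  # singleton grid returns that configuration
  g1 <- grid_search(list(a = 1), function(cell, f) 0.5, folds = 2)
  expect_equal(g1$best$a, 1)
  # cell count is the product of axis sizes
  g2 <- grid_search(list(a = 1:3, b = c("x", "y")),
                    function(cell, f) as.numeric(cell$a == 2 && cell$b == "y"),
                    folds = 3)
  expect_equal(nrow(g2$table), 6L)
  expect_equal(g2$best$a, 2)
  expect_equal(g2$best$b, "y")
  # a planted dominant configuration is always selected
  withr::with_seed(5, {
    metric_fn <- function(cell, f) {
      base <- runif(1, 0, 0.5)
      if (cell$a == 7 && cell$b == 0.1) base + 0.5 else base
    }
    g3 <- grid_search(list(a = c(3, 7, 9), b = c(0.1, 0.9)), metric_fn, folds = 3)
    expect_equal(g3$best$a, 7)
    expect_equal(g3$best$b, 0.1)
  })
  # exact ties resolve to the lexicographically first cell
  g4 <- grid_search(list(a = 1:4), function(cell, f) 1, folds = 2)
  expect_equal(g4$best$a, 1)
  expect_error(grid_search(list(), function(cell, f) 1), "non-empty")
})

test_that("training is deterministic and logs the schedule learning rate", {
  dsd <- generate_dataset(default_leaf_specs()[c("black_spot", "rust")],
                          8, size = 16, seed = 5, out_dir = NULL)
  m <- split_manifest(dsd$manifest, c(0.5, 0.25, 0.25), seed = 5)
  cfg <- leafpad_config(
    model = list(layers = 1L, heads = 1L, head_dim = 8L, ffn_hidden = 16L,
                 image_size = 16L, patch = 8L, n_classes = 2L),
    train = list(batch = 4L),
    loss = list(mode = "parallel"))
  f1 <- train_classifier(m, cfg, epochs = 2, seed = 7, images = dsd$images)
  f2 <- train_classifier(m, cfg, epochs = 2, seed = 7, images = dsd$images)
  expect_identical(f1$final_params, f2$final_params)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$history$lr, lr_at_epoch(0:1, cfg$train$base_lr))
})

test_that("parallel mode with lambda (1,0,0) matches plain cross-entropy exactly", {
  dsd <- generate_dataset(default_leaf_specs()[c("black_spot", "rust")],
                          8, size = 16, seed = 6, out_dir = NULL)
  m <- split_manifest(dsd$manifest, c(0.5, 0.25, 0.25), seed = 6)
  base_model <- list(layers = 1L, heads = 1L, head_dim = 8L, ffn_hidden = 16L,
                     image_size = 16L, patch = 8L, n_classes = 2L)
  cfg_par <- leafpad_config(model = base_model, train = list(batch = 4L),
                            loss = list(mode = "parallel",
                                        weights = c(1, 0, 0)))
  cfg_ce <- leafpad_config(model = base_model, train = list(batch = 4L),
                           loss = list(mode = "cross_entropy"))
  f_par <- train_classifier(m, cfg_par, epochs = 2, seed = 9, images = dsd$images)
  f_ce <- train_classifier(m, cfg_ce, epochs = 2, seed = 9, images = dsd$images)
  expect_identical(f_par$final_params, f_ce$final_params)
  expect_equal(f_par$history$train_loss, f_ce$history$train_loss)
  # and the untrained discriminator is untouched when lambda_adv = 0
  expect_identical(f_par$disc,
                   leafpad:::disc_init(16L, 3L, seed = leafpad:::derive_seed(9, "disc")))
})

test_that("evaluation produces a full metrics report from a trained model", {
  dsd <- generate_dataset(default_leaf_specs()[c("black_spot", "powdery_mildew")],
                          10, size = 16, seed = 8, out_dir = NULL)
  m <- split_manifest(dsd$manifest, c(0.6, 0.2, 0.2), seed = 8)
  cfg <- leafpad_config(
    model = list(layers = 1L, heads = 2L, head_dim = 8L, ffn_hidden = 32L,
                 image_size = 16L, patch = 8L, n_classes = 2L),
    train = list(batch = 4L),
    loss = list(mode = "cross_entropy"), augment = list(p = 0))
  fit <- train_classifier(m, cfg, epochs = 3, seed = 1, images = dsd$images)
  mr <- evaluate_model(fit, m, split = "test", images = dsd$images)
  expect_s3_class(mr, "metrics_report")
  expect_equal(sum(mr$confusion), sum(m$split == "test"))
  expect_true(all(!is.na(mr$accuracy)))
  pred <- predict(fit, m[m$split == "test", ], images = dsd$images)
  expect_length(pred, sum(m$split == "test"))
  probs <- predict(fit, m[m$split == "test", ], type = "prob", images = dsd$images)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
})

test_that("checkpoints roundtrip through disk", {
  dsd <- generate_dataset(default_leaf_specs()[c("black_spot", "rust")],
                          6, size = 16, seed = 9, out_dir = NULL)
  m <- split_manifest(dsd$manifest, c(0.5, 0.25, 0.25), seed = 9)
  cfg <- leafpad_config(
    model = list(layers = 1L, heads = 1L, head_dim = 4L, ffn_hidden = 8L,
                 image_size = 16L, patch = 8L, n_classes = 2L),
    train = list(batch = 4L), loss = list(mode = "cross_entropy"))
  fit <- train_classifier(m, cfg, epochs = 1, seed = 2, images = dsd$images)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, fit$params)
})
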