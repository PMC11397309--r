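# Training and evaluation of the parallel-attention classifier. The fit
# returns a classed model object with print/summary/predict/plot methods.

# load every manifest image into memory as integer arrays; soft labels are
# taken from p0..p<K-1> columns when present, else one-hot from `label`
load_dataset <- function(m, cfg, images = NULL) {
  K <- cfg$model$n_classes
  n <- nrow(m)
  I <- cfg$model$image_size
  rasters <- vector("list", n)
  for (i in seq_len(n)) {
    img <- if (!is.null(images)) images[[m$path[i]]] else load_image(m$path[i])
    d <- dim(img)
    if (d[1] != I || d[2] != I || d[3] != cfg$model$channels) {
      stop(sprintf("image %s is %dx%dx%d but the model expects %dx%dx%d",
                   m$path[i], d[1], d[2], d[3], I, I, cfg$model$channels),
           call. = FALSE)
    }
    rasters[[i]] <- unclass(img)
  }
  soft_cols <- paste0("p", 0:(K - 1L))
  labels <- if (all(soft_cols %in% names(m))) {
    as.matrix(as.data.frame(m)[, soft_cols])
  } else {
    lab <- matrix(0, n, K)
    lab[cbind(seq_len(n), m$label + 1L)] <- 1
    lab
  }
  list(rasters = rasters, labels = labels, split = m$split,
       hard = m$label, n = n)
}

rasters_to_tensor4 <- function(rasters, idx, L = 256) {
  d <- dim(rasters[[idx[1]]])
  x4 <- array(0, dim = c(d, length(idx)))
  for (j in seq_along(idx)) x4[, , , j] <- rasters[[idx[j]]]
  2 * x4 / (L - 1) - 1
}

# per-image pixel-space augmentation inside the training loop; draws
# parameters from the current RNG stream
augment_batch <- function(rasters, labels, idx, train_idx, acfg) {
  out_r <- vector("list", length(idx))
  out_l <- labels[idx, , drop = FALSE]
  d <- dim(rasters[[idx[1]]])
  for (j in seq_along(idx)) {
    r <- rasters[[idx[j]]]
    lab <- out_l[j, ]
    if (stats::runif(1) < acfg$p) {
      op <- acfg$ops[sample.int(length(acfg$ops), 1L)]
      af <- stats::runif(1, acfg$area[1], acfg$area[2])
      ms <- sample.int(2147483646L, 1L)
      if (op == "cutout") {
        mask <- make_box_mask(d[1], d[2], af, seed = ms)
        r <- unclass(cutout(raster_image(r), mask))
      } else if (op == "cutmix") {
        partner <- train_idx[sample.int(length(train_idx), 1L)]
        mask <- make_box_mask(d[1], d[2], af, seed = ms)
        mix <- cutmix(soft_labeled(raster_image(r), lab),
                      soft_labeled(raster_image(rasters[[partner]]),
                                   labels[partner, ]),
                      mask)
        r <- unclass(mix$image); lab <- mix$label
      } else if (op == "mosaic") {
        others <- train_idx[sample.int(length(train_idx), 3L, replace = TRUE)]
        quads <- c(list(soft_labeled(raster_image(r), lab)),
                   lapply(others, function(o) {
                     soft_labeled(raster_image(rasters[[o]]), labels[o, ])
                   }))
        mz <- mosaic(quads, seed = sample.int(2147483646L, 1L))
        r <- unclass(mz$image); lab <- mz$label
      }
    }
    out_r[[j]] <- r
    out_l[j, ] <- lab
  }
  list(rasters = out_r, labels = out_l)
}

# replace selected tensors by diffusion round-trips (forward-noise to
# t_inj, then denoise back), keeping their labels
diffusion_inject <- function(x4, diffusion, ratio) {
  B <- dim(x4)[4]
  n_inj <- floor(ratio * B)
  if (n_inj < 1L) return(x4)
  pick <- sample.int(B, n_inj)
  sched <- diffusion$sched
  t_inj <- max(1L, round(sched$T / 4))
  for (b in pick) {
    st <- forward_marginal(x4[, , , b], t_inj, sched)
    x <- st$x
    for (t in seq(t_inj, 1L)) {
      fw <- denoiser_fwd(array(x, dim = c(dim(x), 1L)), t, diffusion$params)
      x <- reverse_mean(x, t, fw$eps[, , , 1L], sched)
    }
    x4[, , , b] <- pmin(pmax(x, -1), 1)
  }
  x4
}

#' Train the parallel-attention classifier
#'
#' Seeded training loop: per-batch pixel-space augmentation, optional
#' diffusion-generated sample injection, forward pass, composite loss,
#' SGD with momentum under the exponential learning-rate schedule
#' ([lr_at_epoch()]) and L2 weight decay. The discriminator of the
#' adversarial component exists only in parallel loss mode, is initialized
#' from an independent seed stream and is updated (once per generator step)
#' only when \code{lambda_adv > 0}, so runs with
#' \code{weights = c(1, 0, 0)} are bit-identical to plain cross-entropy
#' runs. Per-epoch train/val losses and metrics are recorded and the
#' best-validation-accuracy parameters retained.
#'
#' @param m [manifest()] with train and val splits assigned.
#' @param config [leafpad_config()].
#' @param epochs,batch optional overrides of the config values.
#' @param seed integer master seed; all randomness derives from it.
#' @param diffusion optional list(params, sched) of a trained denoiser for
#'   sample injection at \code{config$augment$diffusion_ratio}.
#' @param images optional named list (by path) of preloaded
#'   [raster_image()]s to skip disk IO.
#' @param verbose print per-epoch progress.
#' @return object of class \code{leafpad_model}: list with \code{params}
#'   (best-validation), \code{final_params}, \code{acfg} (the
#'   [attention_config()]), \code{config}, \code{history} (data.frame),
#'   \code{loss_fn} spec, \code{seed}, \code{disc} (discriminator
#'   parameters or NULL), \code{class_names}.
#' @export
train_classifier <- function(m, config = leafpad_config(), epochs = NULL,
                             batch = NULL, seed = 0L, diffusion = NULL,
                             images = NULL, verbose = FALSE) {
  epochs <- if (!is.null(epochs)) epochs else config$train$epochs
  batch <- if (!is.null(batch)) batch else config$train$batch
  acfg <- model_attention_config(config)
  ds <- load_dataset(m, config, images)
  train_idx <- which(ds$split == "train")
  val_idx <- which(ds$split == "val")
  if (length(train_idx) == 0L || length(val_idx) == 0L) {
    stop("manifest needs non-empty train and val splits", call. = FALSE)
  }
  mode <- config$loss$mode
  lw <- do.call(loss_weights, as.list(unname(config$loss$weights)))
  lfn <- loss_mode(mode, gamma = config$loss$gamma, lw = lw)
  use_recon <- mode == "parallel" && lw["recon"] > 0
  use_adv <- mode == "parallel" && lw["adv"] > 0
  cross <- acfg$attention_mode == "cross"
  params <- transformer_init(acfg, seed = derive_seed(seed, "init"))
  disc <- if (mode == "parallel") {
    disc_init(acfg$image_size, acfg$channels, seed = derive_seed(seed, "disc"))
  } else NULL
  enh_rasters <- NULL
  if (cross) {
    enh_rasters <- lapply(ds$rasters, function(r) {
      unclass(equalize_hist(raster_image(r)))
    })
  }
  opt_state <- NULL
  disc_state <- NULL
  history <- data.frame()
  best <- list(acc = -Inf, params = params)
  wd <- config$train$weight_decay
  mom <- config$train$momentum
  optimizer <- if (is.null(config$train$optimizer)) "adam" else config$train$optimizer
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      lr <- lr_at_epoch(ep - 1L, config$train$base_lr)
      ord <- sample(train_idx)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = batch)) {
        idx <- ord[start:min(start + batch - 1L, length(ord))]
        aug <- augment_batch(ds$rasters, ds$labels, idx, train_idx, config$augment)
        d0 <- dim(aug$rasters[[1]])
        x4 <- array(0, dim = c(d0, length(idx)))
        for (j in seq_along(idx)) x4[, , , j] <- aug$rasters[[j]]
        x4 <- 2 * x4 / 255 - 1
        if (!is.null(diffusion) && config$augment$diffusion_ratio > 0) {
          x4 <- diffusion_inject(x4, diffusion, config$augment$diffusion_ratio)
        }
        enh4 <- NULL
        if (cross) {
          enh4 <- array(0, dim = dim(x4))
          for (j in seq_along(idx)) enh4[, , , j] <- 2 * enh_rasters[[idx[j]]] / 255 - 1
        }
        fw <- transformer_fwd(x4, acfg, params, training = TRUE, enh4 = enh4)
        sc_fake <- NULL; dfw <- NULL
        if (use_adv) {
          dfw <- disc_fwd(fw$recon, disc)
          sc_fake <- dfw$score
        }
        ls <- lfn(fw$logits, aug$labels,
                  reconstruction = if (use_recon || use_adv) fw$recon else NULL,
                  input_img = x4, disc_score_fake = sc_fake)
        drecon <- ls$drecon
        if (use_adv) {
          db <- disc_bwd(ls$dscore, dfw$cache, disc)
          drecon <- if (is.null(drecon)) db$dx else drecon + db$dx
        }
        grads <- transformer_bwd(ls$dlogits, drecon, fw$cache)
        st <- optim_step(optimizer, params, grads, opt_state, lr = lr,
                         momentum = mom, weight_decay = wd)
        params <- st$params; opt_state <- st$state
        if (use_adv) {
          # discriminator update on real inputs vs detached reconstructions
          fr <- disc_fwd(x4, disc)
          ff <- disc_fwd(fw$recon, disc)
          B <- length(fr$score)
          ds_real <- -(1 - stats::plogis(fr$score)) / B
          ds_fake <- stats::plogis(ff$score) / B
          gr <- disc_bwd(ds_real, fr$cache, disc)$grads
          gf <- disc_bwd(ds_fake, ff$cache, disc)$grads
          gd <- tree_map(`+`, gr, gf)
          dst <- optim_step(optimizer, disc, gd, disc_state, lr = lr,
                            momentum = mom, weight_decay = wd)
          atts <- attributes(disc)
          disc <- dst$params; attributes(disc) <- atts
          disc_state <- dst$state
        }
        ep_loss <- ep_loss + ls$total; nb <- nb + 1L
      }
      val <- eval_on_indices(ds, val_idx, acfg, params,
                             enh_rasters = enh_rasters, lfn = lfn)
      history <- rbind(history,
                       data.frame(epoch = ep, lr = lr,
                                  train_loss = ep_loss / nb,
                                  val_loss = val$loss,
                                  val_accuracy = val$accuracy))
      if (val$accuracy > best$acc) {
        best <- list(acc = val$accuracy, params = params)
      }
      if (verbose) {
        message(sprintf("epoch %3d lr %.5f train %.4f val %.4f acc %.3f",
                        ep, lr, ep_loss / nb, val$loss, val$accuracy))
      }
    }
  })
  structure(list(params = best$params, final_params = params, acfg = acfg,
                 config = config, history = history,
                 loss = list(mode = mode, gamma = config$loss$gamma, weights = lw),
                 seed = seed, disc = disc,
                 class_names = attr(m, "class_names")),
            class = "leafpad_model")
}

# forward a set of images in evaluation mode, in chunks
eval_on_indices <- function(ds, idx, acfg, params, enh_rasters = NULL,
                            lfn = NULL, chunk = 32L) {
  n <- length(idx)
  K <- acfg$n_classes
  logits <- matrix(0, n, K)
  loss <- 0; nb <- 0L
  for (start in seq(1L, n, by = chunk)) {
    sub <- idx[start:min(start + chunk - 1L, n)]
    x4 <- rasters_to_tensor4(ds$rasters, sub)
    enh4 <- NULL
    if (!is.null(enh_rasters)) {
      enh4 <- array(0, dim = dim(x4))
      for (j in seq_along(sub)) enh4[, , , j] <- 2 * enh_rasters[[sub[j]]] / 255 - 1
    }
    fw <- transformer_fwd(x4, acfg, params, training = FALSE, enh4 = enh4)
    logits[(start:(start + length(sub) - 1L)), ] <- fw$logits
    if (!is.null(lfn)) {
      ls <- lfn(fw$logits, ds$labels[sub, , drop = FALSE])
      loss <- loss + ls$total; nb <- nb + 1L
    }
  }
  pred <- max.col(logits, ties.method = "first") - 1L
  list(logits = logits, pred = pred,
       accuracy = mean(pred == ds$hard[idx]),
       loss = if (nb > 0) loss / nb else NA_real_)
}

#' Evaluate a trained model on a manifest split
#'
#' Runs the classifier on every record of the chosen split and returns the
#' full [metrics_report()] (confusion matrix, per-class and macro
#' precision/recall/F1, accuracy, one-vs-rest ROC and PR curves from the
#' softmax scores).
#'
#' @param model [train_classifier()] fit.
#' @param m manifest.
#' @param split which split to evaluate (default "test").
#' @param images optional preloaded images (named by path).
#' @return [metrics_report()].
#' @export
evaluate_model <- function(model, m, split = "test", images = NULL) {
  sel <- m[m$split == split, , drop = FALSE]
  attr(sel, "class_names") <- attr(m, "class_names")
  if (nrow(sel) == 0L) stop("split is empty", call. = FALSE)
  ds <- load_dataset(sel, model$config, images)
  enh_rasters <- if (model$acfg$attention_mode == "cross") {
    lapply(ds$rasters, function(r) unclass(equalize_hist(raster_image(r))))
  } else NULL
  ev <- eval_on_indices(ds, seq_len(ds$n), model$acfg, model$params,
                        enh_rasters = enh_rasters)
  scores <- nn_softmax(ev$logits)
  metrics_report(ds$hard, ev$pred, scores = scores,
                 n_classes = model$acfg$n_classes,
                 class_names = model$class_names)
}

#' @export
print.leafpad_model <- function(x, ...) {
  cat(sprintf("<leafpad_model: %d-layer %s-attention Transformer, %d branches, %s loss>\n",
              x$acfg$layers, x$acfg$attention_mode, x$acfg$n_branches,
              x$loss$mode))
  cat(sprintf("  d_model %d (%d heads x %d), %d tokens of %dx%d patches, %d classes\n",
              x$acfg$d_model, x$acfg$heads, x$acfg$head_dim, x$acfg$n_tokens,
              x$acfg$patch, x$acfg$patch, x$acfg$n_classes))
  cat(sprintf("  %d parameters; trained %d epochs; best val accuracy %.4f\n",
              n_params(x$params), nrow(x$history), max(x$history$val_accuracy)))
  invisible(x)
}

#' @export
summary.leafpad_model <- function(object, ...) {
  print(object)
  h <- object$history
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(h, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.leafpad_model <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training / validation loss")
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", legend = c("train", "val"), lty = 1:2, bty = "n")
  graphics::plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
                 ylab = "accuracy", main = "validation accuracy")
  invisible(x)
}

#' Predict from a trained classifier
#'
#' @param object [train_classifier()] fit.
#' @param newdata a manifest, a single [raster_image()], or a list of them.
#' @param type \code{"class"} (integer labels), \code{"prob"} (softmax
#'   matrix), \code{"logits"}, or \code{"recon"} (reconstructions).
#' @param images optional preloaded images for a manifest `newdata`.
#' @param ... unused.
#' @export
predict.leafpad_model <- function(object, newdata, type = c("class", "prob", "logits", "recon"),
                                  images = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "raster_image")) newdata <- list(newdata)
  if (inherits(newdata, "leaf_manifest")) {
    ds <- load_dataset(newdata, object$config, images)
    rasters <- ds$rasters
  } else {
    rasters <- lapply(newdata, unclass)
  }
  n <- length(rasters)
  x4 <- array(0, dim = c(dim(rasters[[1]]), n))
  for (j in seq_len(n)) x4[, , , j] <- rasters[[j]]
  x4 <- 2 * x4 / 255 - 1
  enh4 <- NULL
  if (object$acfg$attention_mode == "cross") {
    enh4 <- array(0, dim = dim(x4))
    for (j in seq_len(n)) {
      enh4[, , , j] <- 2 * unclass(equalize_hist(raster_image(rasters[[j]]))) / 255 - 1
    }
  }
  fw <- transformer_fwd(x4, object$acfg, object$params, training = FALSE,
                        enh4 = enh4)
  switch(type,
         class = max.col(fw$logits, ties.method = "first") - 1L,
         prob = nn_softmax(fw$logits),
         logits = fw$logits,
         recon = fw$recon)
}

#' Save / load a model checkpoint
#'
#' Single-file archive (RDS) holding the configuration, parameters and
#' history with a format-version field.
#'
#' @param model [train_classifier()] fit (or any list with params).
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version)) stop("not a checkpoint file", call. = FALSE)
  ck$model
}
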