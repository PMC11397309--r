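# Training objectives. Classification losses take a logits matrix (B x K)
# and a soft-label matrix of the same shape; every loss returns its value
# together with the gradient w.r.t. the logits so the training loop stays
# framework-free.

softmax_rows <- function(z) nn_softmax(z)

#' Loss-component weights
#'
#' @param lambda_cls,lambda_recon,lambda_adv nonnegative weights of the
#'   classification, reconstruction and adversarial components (defaults
#'   1.0, 0.5, 0.1).
#' @return named numeric vector of class \code{loss_weights}.
#' @export
loss_weights <- function(lambda_cls = 1.0, lambda_recon = 0.5, lambda_adv = 0.1) {
  w <- c(cls = lambda_cls, recon = lambda_recon, adv = lambda_adv)
  if (any(w < 0)) stop("loss weights must be nonnegative", call. = FALSE)
  if (all(w == 0)) stop("at least one loss weight must be positive", call. = FALSE)
  structure(w, class = "loss_weights")
}

# soft-label cross-entropy, mean over the batch
ce_loss <- function(logits, labels) {
  p <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -sum(labels * log(p + eps)) / nrow(logits)
  list(loss = loss, dlogits = (p - labels) / nrow(logits))
}

# focal loss on the true-class probability p_t = sum_k label_k p_k
focal_loss <- function(logits, labels, gamma = 2) {
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  p <- softmax_rows(logits)
  eps <- 1e-12
  pt <- rowSums(labels * p)
  pt <- pmin(pmax(pt, eps), 1)
  loss <- mean(-(1 - pt)^gamma * log(pt))
  dpt <- ifelse(pt >= 1, -1,
                gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt)
  # dpt/dz_j = p_j (label_j - pt)
  dlogits <- (dpt / nrow(logits)) * p * (labels - pt)
  list(loss = loss, dlogits = dlogits)
}

#' Composite (parallel) training loss
#'
#' Weighted sum of three components:
#' classification (soft-label cross-entropy of the softmaxed logits),
#' reconstruction (mean squared error between reconstruction and input),
#' and adversarial (non-saturating generator loss
#' \code{-log sigmoid(disc_score_fake)}):
#' \code{total = lambda_cls L_cls + lambda_recon L_recon + lambda_adv L_adv}.
#' Totals are exactly linear in each lambda.
#'
#' @param logits B x K logit matrix (or length-K vector).
#' @param soft_label matching soft-label matrix/vector.
#' @param reconstruction,input_img reconstruction and its target (any equal
#'   shape); may be NULL when \code{lambda_recon = 0}.
#' @param disc_score_fake discriminator scores on the reconstructions
#'   (length B); may be NULL when \code{lambda_adv = 0}.
#' @param lw [loss_weights()].
#' @return list(total, components = c(cls, recon, adv), gradients
#'   \code{dlogits}, \code{drecon}, \code{dscore}).
#' @export
parallel_loss <- function(logits, soft_label, reconstruction = NULL,
                          input_img = NULL, disc_score_fake = NULL,
                          lw = loss_weights()) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  if (is.null(dim(soft_label))) soft_label <- matrix(soft_label, nrow = 1)
  if (!identical(dim(logits), dim(soft_label))) {
    stop("logits and soft_label shapes differ", call. = FALSE)
  }
  cls <- ce_loss(logits, soft_label)
  l_recon <- 0; drecon <- NULL
  if (!is.null(reconstruction)) {
    if (!identical(dim(unclass(reconstruction)), dim(unclass(input_img)))) {
      stop("reconstruction and input shapes differ", call. = FALSE)
    }
    diffr <- unclass(reconstruction) - unclass(input_img)
    l_recon <- mean(diffr^2)
    drecon <- 2 * diffr / length(diffr)
  }
  l_adv <- 0; dscore <- NULL
  if (!is.null(disc_score_fake)) {
    s <- as.numeric(disc_score_fake)
    # -log sigmoid(s) = softplus(-s), computed stably
    l_adv <- mean(ifelse(s > 0, log1p(exp(-s)), -s + log1p(exp(s))))
    dscore <- (stats::plogis(s) - 1) / length(s)
  }
  total <- lw["cls"] * cls$loss + lw["recon"] * l_recon + lw["adv"] * l_adv
  list(total = unname(total),
       components = c(cls = cls$loss, recon = l_recon, adv = l_adv),
       dlogits = lw["cls"] * cls$dlogits,
       drecon = if (!is.null(drecon)) unname(lw["recon"]) * drecon else NULL,
       dscore = if (!is.null(dscore)) unname(lw["adv"]) * dscore else NULL)
}

#' Select a classification loss mode
#'
#' \code{"cross_entropy"} is the plain soft-label cross-entropy;
#' \code{"focal"} down-weights easy examples by \code{(1 - p_t)^gamma}
#' (gamma = 0 recovers cross-entropy exactly); \code{"parallel"} is the
#' composite [parallel_loss()].
#'
#' @param mode one of \code{"cross_entropy"}, \code{"focal"},
#'   \code{"parallel"}.
#' @param gamma focal exponent, >= 0.
#' @param lw [loss_weights()] for parallel mode.
#' @return function(logits, labels, reconstruction, input_img,
#'   disc_score_fake) returning the [parallel_loss()]-shaped list.
#' @export
loss_mode <- function(mode = c("cross_entropy", "focal", "parallel"),
                      gamma = 2, lw = loss_weights()) {
  mode <- match.arg(mode)
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  switch(mode,
    cross_entropy = function(logits, labels, reconstruction = NULL,
                             input_img = NULL, disc_score_fake = NULL) {
      r <- ce_loss(as_mat(logits), as_mat(labels))
      list(total = r$loss, components = c(cls = r$loss, recon = 0, adv = 0),
           dlogits = r$dlogits, drecon = NULL, dscore = NULL)
    },
    focal = function(logits, labels, reconstruction = NULL,
                     input_img = NULL, disc_score_fake = NULL) {
      r <- focal_loss(as_mat(logits), as_mat(labels), gamma)
      list(total = r$loss, components = c(cls = r$loss, recon = 0, adv = 0),
           dlogits = r$dlogits, drecon = NULL, dscore = NULL)
    },
    parallel = function(logits, labels, reconstruction = NULL,
                        input_img = NULL, disc_score_fake = NULL) {
      parallel_loss(logits, labels, reconstruction, input_img,
                    disc_score_fake, lw)
    })
}

as_mat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else x

#' Learning-rate schedule
#'
#' Exponential decay from the base rate: 10% reduction every 10 epochs,
#' \code{base * 0.9^floor(epoch / 10)} (epoch 0 is the first).
#'
#' @param epoch epoch index, >= 0.
#' @param base initial learning rate (default 0.001).
#' @return learning rate.
#' @export
lr_at_epoch <- function(epoch, base = 0.001) {
  if (any(epoch < 0)) stop("epoch must be nonnegative", call. = FALSE)
  base * 0.9^floor(epoch / 10)
}
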