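# Adversarial component of the composite loss: a small strided-conv
# discriminator scoring images (reconstructions vs. real inputs), trained
# with the non-saturating GAN objective, one discriminator update per
# generator step.

#' Initialize the reconstruction discriminator
#'
#' Three 3x3 stride-2 convolutions (padding 1) with ReLU, widths
#' \code{widths}, then a linear map of the flattened features to a single
#' real-valued score.
#'
#' @param image_size input side (must be divisible by 8).
#' @param channels input channels.
#' @param widths channel widths of the three conv layers.
#' @param seed seed for the Gaussian init.
#' @return parameter list of class \code{disc_params}.
#' @export
disc_init <- function(image_size, channels = 3L, widths = c(8L, 16L, 32L),
                      seed = 0L) {
  if (image_size %% 8L != 0L) stop("image_size must be divisible by 8", call. = FALSE)
  feat <- (image_size %/% 8L)^2 * widths[3]
  with_seed(seed, {
    cin <- c(channels, widths[1], widths[2])
    p <- list(convs = lapply(1:3, function(i) {
                list(W = rnorm_mat(9L * cin[i], widths[i], 0.05 / sqrt(cin[i])),
                     b = numeric(widths[i]))
              }),
              out = list(W = rnorm_mat(feat, 1L, 0.02), b = numeric(1)))
    attr(p, "image_size") <- as.integer(image_size)
    class(p) <- "disc_params"
    p
  })
}

disc_fwd <- function(x4, params) {
  a <- x4
  caches <- vector("list", 3L)
  for (i in 1:3) {
    cv <- conv2d_fwd(a, params$convs[[i]]$W, params$convs[[i]]$b,
                     k = 3L, stride = 2L, pad = 1L)
    r <- nn_relu_fwd(cv$y)
    caches[[i]] <- list(cv = cv, mask = r$cache)
    a <- r$y
  }
  d <- dim(a)
  B <- d[4]
  flat <- matrix(0, B, prod(d[1:3]))
  for (bb in seq_len(B)) flat[bb, ] <- as.vector(a[, , , bb])
  outf <- nn_linear_fwd(flat, params$out$W, params$out$b)
  list(score = as.vector(outf$y),
       cache = list(caches = caches, outf = outf, dfeat = d))
}

disc_bwd <- function(dscore, cache, params) {
  B <- length(dscore)
  outb <- nn_linear_bwd(matrix(dscore, ncol = 1L), cache$outf$cache)
  d <- cache$dfeat
  da <- array(0, dim = d)
  for (bb in seq_len(B)) da[, , , bb] <- array(outb$dx[bb, ], dim = d[1:3])
  gconvs <- vector("list", 3L)
  for (i in 3:1) {
    da <- nn_relu_bwd(da, cache$caches[[i]]$mask)
    cb <- conv2d_bwd(da, cache$caches[[i]]$cv$cache)
    gconvs[[i]] <- list(W = cb$dW, b = cb$db)
    da <- cb$dx
  }
  list(grads = list(convs = gconvs,
                    out = list(W = outb$dW, b = outb$db)),
       dx = da)
}
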