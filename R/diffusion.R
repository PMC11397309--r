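# Forward/reverse denoising diffusion. The default ("literal") convention
# implements the chain exactly as its printed parameterization:
#   q(x_t | x_{t-1}) = N(alpha_t x_{t-1}, (1 - alpha_t) I)
#   x_{t-1} = (1/alpha_t) (x_t - ((1 - alpha_t)/sqrt(1 - alpha_t^2)) eps_hat)
# which differs from the standard DDPM sqrt-scaling; a "ddpm" convention is
# provided for comparison. Marginal moments follow the recursions
#   m_t = prod_{s<=t} c_s,   v_t = c_t^2 v_{t-1} + (1 - alpha_t),  v_0 = 0
# with per-step mean coefficient c_t = alpha_t (literal) or sqrt(alpha_t)
# (ddpm).

#' Noise schedule
#'
#' Linear interpolation of the per-step coefficient alpha_t from
#' `alpha_start` to `alpha_end` over T steps, with precomputed marginal
#' moments (m_t, v_t).
#'
#' @param T step count (default 64).
#' @param convention \code{"literal"} (mean coefficient alpha_t, as printed)
#'   or \code{"ddpm"} (mean coefficient sqrt(alpha_t)).
#' @param alpha_start,alpha_end schedule endpoints, with
#'   \code{0 < alpha_end <= alpha_start <= 1}.
#' @return list of class \code{noise_schedule} with fields \code{T},
#'   \code{alpha}, \code{ct} (per-step mean coefficient), \code{m}
#'   (marginal mean coefficient), \code{v} (marginal variance),
#'   \code{convention}.
#' @export
make_schedule <- function(T = 64L, convention = c("literal", "ddpm"),
                          alpha_start = 0.999, alpha_end = 0.95) {
  convention <- match.arg(convention)
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  if (!(alpha_end > 0 && alpha_end <= alpha_start && alpha_start <= 1)) {
    stop("need 0 < alpha_end <= alpha_start <= 1", call. = FALSE)
  }
  alpha <- if (T == 1L) alpha_start else {
    alpha_start + (alpha_end - alpha_start) * (seq_len(T) - 1) / (T - 1)
  }
  ct <- if (convention == "literal") alpha else sqrt(alpha)
  m <- cumprod(ct)
  v <- numeric(T)
  vprev <- 0
  for (t in seq_len(T)) {
    v[t] <- ct[t]^2 * vprev + (1 - alpha[t])
    vprev <- v[t]
  }
  structure(list(T = as.integer(T), alpha = alpha, ct = ct, m = m, v = v,
                 convention = convention),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule: %d steps, %s convention, alpha %.4f..%.4f, m_T=%.4f, v_T=%.4f>\n",
              x$T, x$convention, x$alpha[1], x$alpha[x$T], x$m[x$T], x$v[x$T]))
  invisible(x)
}

#' Diffusion chain state
#'
#' @param x image array (tensor-image scale).
#' @param t step index in \code{0..T}; 0 is the clean-image domain, T the
#'   near-pure-noise domain.
#' @return list of class \code{diffusion_state}.
#' @export
diffusion_state <- function(x, t = 0L) {
  structure(list(x = unclass(x), t = as.integer(t)), class = "diffusion_state")
}

#' One forward (noising) diffusion step
#'
#' Draws \code{x_t = c_t x_{t-1} + sqrt(1 - alpha_t) eps} with standard
#' Gaussian \code{eps}, advancing the state from step t-1 to t.
#'
#' @param state [diffusion_state()] at step t-1 < T.
#' @param sched [make_schedule()].
#' @return [diffusion_state()] at step t.
#' @export
forward_step <- function(state, sched) {
  t <- state$t + 1L
  if (t > sched$T) stop("state already at the final step T", call. = FALSE)
  eps <- stats::rnorm(length(state$x))
  dim(eps) <- dim(state$x)
  x <- sched$ct[t] * state$x + sqrt(1 - sched$alpha[t]) * eps
  diffusion_state(x, t)
}

#' Forward marginal q(x_t | x_0)
#'
#' Single-shot draw \code{x_t = m_t x_0 + sqrt(v_t) eps}, distributionally
#' equal to t applications of [forward_step()].
#'
#' @param x0 clean image array (tensor scale).
#' @param t target step in 1..T.
#' @param sched [make_schedule()].
#' @param eps optional fixed noise draw (for reproducible tests).
#' @return [diffusion_state()] at step t.
#' @export
forward_marginal <- function(x0, t, sched, eps = NULL) {
  if (t < 1L || t > sched$T) stop("t must lie in 1..T", call. = FALSE)
  x0 <- unclass(x0)
  if (is.null(eps)) {
    eps <- stats::rnorm(length(x0))
    dim(eps) <- dim(x0)
  }
  diffusion_state(sched$m[t] * x0 + sqrt(sched$v[t]) * eps, t)
}

#' KL divergence of diagonal Gaussians
#'
#' Closed form \code{0.5 (log(vp/vq) + (vq + (mq - mp)^2)/vp - 1)} summed
#' over elements.
#'
#' @param mu_q,var_q moments of q (arrays or scalars; variances > 0).
#' @param mu_p,var_p moments of p.
#' @return nonnegative scalar.
#' @export
gaussian_kl <- function(mu_q, var_q, mu_p, var_p) {
  if (any(var_q <= 0) || any(var_p <= 0)) {
    stop("variances must be positive", call. = FALSE)
  }
  sum(0.5 * (log(var_p / var_q) + (var_q + (mu_q - mu_p)^2) / var_p - 1))
}

# posterior q(x_{t-1} | x_t, x_0) moments for t >= 2 (linear-Gaussian)
posterior_moments <- function(x0, xt, t, sched) {
  s <- 1 - sched$alpha[t]
  vprev <- sched$v[t - 1L]
  var_post <- 1 / (1 / vprev + sched$ct[t]^2 / s)
  mu <- var_post * (sched$m[t - 1L] / vprev * x0 + sched$ct[t] / s * xt)
  list(mu = mu, var = var_post)
}

# reverse-model mean from the predicted noise (the printed denoising relation
# under the literal convention; standard form under ddpm)
reverse_mean <- function(xt, t, eps_hat, sched) {
  a <- sched$alpha[t]
  if (sched$convention == "literal") {
    if (a == 0) stop("alpha_t = 0: reverse mean undefined (division by zero)", call. = FALSE)
    if (a == 1 && any(eps_hat != 0)) {
      stop("alpha_t = 1 with nonzero noise prediction: degenerate denominator", call. = FALSE)
    }
    coef <- if (a == 1) 0 else (1 - a) / sqrt(1 - a^2)
    (xt - coef * eps_hat) / a
  } else {
    if (a == 0) stop("alpha_t = 0: reverse mean undefined", call. = FALSE)
    vt <- sched$v[t]
    if (vt <= 0 && any(eps_hat != 0)) {
      stop("zero marginal variance with nonzero noise prediction", call. = FALSE)
    }
    coef <- if (vt <= 0) 0 else (1 - a) / sqrt(vt)
    (xt - coef * eps_hat) / sqrt(a)
  }
}

#' One reverse (denoising) diffusion step
#'
#' Under the literal convention evaluates, exactly as printed,
#' \deqn{x_{t-1} = (1/\alpha_t) (x_t - ((1-\alpha_t)/\sqrt{1-\alpha_t^2})\,
#'   \hat\epsilon)}
#'
#' @param x_t image array at step t.
#' @param t step in 1..T.
#' @param eps_hat predicted noise (same shape).
#' @param sched [make_schedule()].
#' @return image array at step t-1.
#' @export
reverse_step <- function(x_t, t, eps_hat, sched) {
  if (t < 1L || t > sched$T) stop("t must lie in 1..T", call. = FALSE)
  reverse_mean(unclass(x_t), t, unclass(eps_hat), sched)
}

# ---- convolutional noise-prediction network --------------------------------

sin_embed_dim <- 16L

# sinusoidal embedding of the (integer) step index
timestep_embedding <- function(t, dim = sin_embed_dim) {
  half <- dim %/% 2L
  freqs <- 10000^(-(seq_len(half) - 1) / half)
  ang <- outer(as.numeric(t), freqs)
  cbind(sin(ang), cos(ang))
}

#' Initialize the convolutional denoiser
#'
#' An epsilon-prediction network: 1x1 in-projection C -> F, a body of 3x3
#' convolutions at F channels with ReLU (padding 1, so spatial size is
#' constant), a 1x1 out-projection F -> C, and a sinusoidal timestep
#' embedding projected to a per-channel bias added after the in-projection.
#' F defaults to 128.
#'
#' @param channels input/output image channels C.
#' @param width internal channel count F (default 128).
#' @param body number of 3x3 body convolutions (default 2).
#' @param seed seed for the Gaussian init.
#' @param init_sd weight standard deviation.
#' @return parameter list of class \code{denoiser_params}.
#' @export
denoiser_init <- function(channels = 3L, width = 128L, body = 2L, seed = 0L,
                          init_sd = 0.05) {
  with_seed(seed, {
    p <- list(
      conv_in = list(W = rnorm_mat(channels, width, init_sd), b = numeric(width)),
      temb = list(W = rnorm_mat(sin_embed_dim, width, init_sd), b = numeric(width)),
      body = lapply(seq_len(body), function(i) {
        list(W = rnorm_mat(9L * width, width, init_sd / sqrt(width)), b = numeric(width))
      }),
      conv_out = list(W = rnorm_mat(width, channels, init_sd), b = numeric(channels))
    )
    attr(p, "channels") <- as.integer(channels)
    attr(p, "width") <- as.integer(width)
    class(p) <- "denoiser_params"
    p
  })
}

# x4: (H, W, C, B); t: step index, scalar or length B
denoiser_fwd <- function(x4, t, params) {
  d <- dim(x4)
  B <- d[4]
  t <- rep_len(as.numeric(t), B)
  cin <- conv2d_fwd(x4, params$conv_in$W, params$conv_in$b, k = 1L)
  te <- timestep_embedding(t)
  tproj <- sweep(te %*% params$temb$W, 2L, params$temb$b, "+")  # B x F
  h <- cin$y
  for (bb in seq_len(B)) {
    h[, , , bb] <- sweep(h[, , , bb, drop = FALSE], 3L, tproj[bb, ], "+")
  }
  bodies <- vector("list", length(params$body))
  a <- h
  for (i in seq_along(params$body)) {
    cv <- conv2d_fwd(a, params$body[[i]]$W, params$body[[i]]$b, k = 3L, pad = 1L)
    r <- nn_relu_fwd(cv$y)
    bodies[[i]] <- list(cv = cv, mask = r$cache)
    a <- r$y
  }
  cout <- conv2d_fwd(a, params$conv_out$W, params$conv_out$b, k = 1L)
  list(eps = cout$y,
       cache = list(cin = cin, te = te, bodies = bodies, cout = cout, B = B))
}

denoiser_bwd <- function(deps, cache, params) {
  coutb <- conv2d_bwd(deps, cache$cout$cache)
  da <- coutb$dx
  gbody <- vector("list", length(params$body))
  for (i in rev(seq_along(params$body))) {
    da <- nn_relu_bwd(da, cache$bodies[[i]]$mask)
    cb <- conv2d_bwd(da, cache$bodies[[i]]$cv$cache)
    gbody[[i]] <- list(W = cb$dW, b = cb$db)
    da <- cb$dx
  }
  B <- cache$B
  dtproj <- matrix(0, B, ncol(params$temb$W))
  for (bb in seq_len(B)) {
    dtproj[bb, ] <- apply(da[, , , bb, drop = FALSE], 3L, sum)
  }
  cinb <- conv2d_bwd(da, cache$cin$cache)
  list(conv_in = list(W = cinb$dW, b = cinb$db),
       temb = list(W = crossprod(cache$te, dtproj), b = colSums(dtproj)),
       body = gbody,
       conv_out = list(W = coutb$dW, b = coutb$db))
}

#' Variational-lower-bound diffusion loss
#'
#' Monte-Carlo estimate of the per-image VLB
#' \deqn{\sum_t KL[q(x_{t-1} | x_t, x_0)\,\|\,p_\theta(x_{t-1} | x_t)]
#'   - \log p_\theta(x_0 | x_1)}
#' with the reverse-model mean given by the denoising relation applied to
#' the predicted noise and its variance fixed to the forward-posterior
#' variance. One step index per batch element is subsampled uniformly (the
#' sum is estimated as T times the sampled term); the t = 1 draw contributes
#' the Gaussian decoder term. Reported per pixel, averaged over the batch.
#'
#' @param x0_4 clean images, \code{(H, W, C, B)} array in tensor scale.
#' @param params [denoiser_init()] parameters.
#' @param sched [make_schedule()] (alpha_t < 1 required).
#' @param t optional fixed step indices (length B) instead of sampling.
#' @param eps optional fixed noise array instead of sampling.
#' @param return_grads also return parameter gradients.
#' @return scalar loss, or list(loss, grads).
#' @export
vlb_loss <- function(x0_4, params, sched, t = NULL, eps = NULL,
                     return_grads = FALSE) {
  d <- dim(x0_4)
  B <- d[4]
  npix <- prod(d[1:3])
  if (is.null(t)) t <- sample.int(sched$T, B, replace = TRUE)
  t <- rep_len(as.integer(t), B)
  if (any(sched$alpha[t] >= 1)) {
    stop("vlb_loss requires alpha_t < 1 at the sampled steps", call. = FALSE)
  }
  if (is.null(eps)) eps <- array(stats::rnorm(length(x0_4)), dim = d)
  xt <- x0_4
  for (bb in seq_len(B)) {
    xt[, , , bb] <- sched$m[t[bb]] * x0_4[, , , bb] +
      sqrt(sched$v[t[bb]]) * eps[, , , bb]
  }
  fw <- denoiser_fwd(xt, t, params)
  loss <- 0
  deps <- array(0, dim = d)
  for (bb in seq_len(B)) {
    a <- sched$alpha[t[bb]]
    ct <- sched$ct[t[bb]]
    c2 <- if (sched$convention == "literal") (1 - a) / sqrt(1 - a^2)
          else (1 - a) / sqrt(sched$v[t[bb]])
    mup <- reverse_mean(xt[, , , bb], t[bb], fw$eps[, , , bb], sched)
    if (t[bb] >= 2L) {
      pm <- posterior_moments(x0_4[, , , bb], xt[, , , bb], t[bb], sched)
      term <- sum((pm$mu - mup)^2) / (2 * pm$var)
      dmup <- (mup - pm$mu) / pm$var
    } else {
      s1 <- 1 - a
      term <- sum((x0_4[, , , bb] - mup)^2) / (2 * s1) +
        0.5 * npix * log(2 * pi * s1)
      dmup <- (mup - x0_4[, , , bb]) / s1
    }
    loss <- loss + sched$T * term / npix
    deps[, , , bb] <- -(c2 / ct) * dmup * sched$T / npix
  }
  loss <- loss / B
  if (!return_grads) return(loss)
  grads <- denoiser_bwd(deps / B, fw$cache, params)
  list(loss = loss, grads = grads)
}

#' Generate images by reverse diffusion
#'
#' Starts from \code{x_T ~ N(0, I)} and applies [reverse_step()] with the
#' denoiser's noise prediction for t = T..1 (exactly T denoiser
#' evaluations), clipping the final output to \code{[-1, 1]}.
#'
#' @param params [denoiser_init()] parameters.
#' @param sched [make_schedule()].
#' @param shape \code{c(H, W, C)} of the sample.
#' @param seed integer seed.
#' @param n number of images.
#' @return \code{(H, W, C, n)} array with attribute \code{n_evals}, the
#'   number of denoiser evaluations performed.
#' @export
sample_diffusion <- function(params, sched, shape, seed = 0L, n = 1L) {
  with_seed(seed, {
    x <- array(stats::rnorm(prod(shape) * n), dim = c(shape, n))
    evals <- 0L
    for (t in seq(sched$T, 1L)) {
      fw <- denoiser_fwd(x, t, params)
      evals <- evals + 1L
      x <- array(reverse_mean(x, t, fw$eps, sched), dim = dim(x))
    }
    x <- pmin(pmax(x, -1), 1)
    dim(x) <- c(shape, n)
    attr(x, "n_evals") <- evals
    x
  })
}

#' Train the denoiser by stochastic VLB descent
#'
#' Plain SGD-with-momentum loop over minibatches of clean images; the
#' per-epoch history loss is evaluated on a fixed noise/step set so epochs
#' are comparable.
#'
#' @param x0s list of clean images (arrays, tensor scale) or an
#'   \code{(H, W, C, N)} array.
#' @param params [denoiser_init()] parameters.
#' @param sched [make_schedule()].
#' @param epochs,batch,lr training loop controls.
#' @param seed integer seed.
#' @return list(params, history) where history is the per-epoch evaluation
#'   loss.
#' @export
train_denoiser <- function(x0s, params, sched, epochs = 10L, batch = 8L,
                           lr = 1e-3, seed = 0L) {
  if (is.list(x0s)) {
    d0 <- dim(x0s[[1]])
    x4 <- array(0, dim = c(d0, length(x0s)))
    for (i in seq_along(x0s)) x4[, , , i] <- unclass(x0s[[i]])
  } else x4 <- x0s
  N <- dim(x4)[4]
  eval_t <- with_seed(derive_seed(seed, "vlb-eval-t"),
                      sample.int(sched$T, N, replace = TRUE))
  eval_eps <- with_seed(derive_seed(seed, "vlb-eval-eps"),
                        array(stats::rnorm(length(x4)), dim = dim(x4)))
  history <- numeric(epochs)
  state <- NULL
  attrs <- attributes(params)
  p <- unclass(params)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      for (start in seq(1L, N, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, N)]
        xb <- x4[, , , idx, drop = FALSE]
        lg <- vlb_loss(xb, p, sched, return_grads = TRUE)
        st <- sgd_step(p, lg$grads, state, lr = lr)
        p <- st$params
        state <- st$state
      }
      history[ep] <- vlb_loss(x4, p, sched, t = eval_t, eps = eval_eps)
    }
  })
  attributes(p) <- attrs
  list(params = p, history = history)
}
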