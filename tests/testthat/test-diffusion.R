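test_that("schedules precompute marginal moments by their recursions", {
  s1 <- make_schedule(T = 1, alpha_start = 1, alpha_end = 1)
  expect_equal(s1$m, 1)
  expect_equal(s1$v, 0)
  sd <- make_schedule()
  expect_equal(sd$T, 64L)
  expect_length(sd$alpha, 64L)
  # v recursion equals the unrolled closed form for random schedules
  withr::with_seed(21, {
    for (rep in 1:5) {
      Tn <- sample(3:10, 1)
      a_hi <- runif(1, 0.9, 1); a_lo <- runif(1, 0.5, a_hi)
      s <- make_schedule(Tn, alpha_start = a_hi, alpha_end = a_lo)
      for (t in seq_len(Tn)) {
        closed <- sum(vapply(seq_len(t), function(ss) {
          tail_prod <- if (ss < t) prod(s$ct[(ss + 1):t]^2) else 1
          (1 - s$alpha[ss]) * tail_prod
        }, numeric(1)))
        expect_equal(s$v[t], closed, tolerance = 1e-12)
      }
      expect_true(all(diff(s$m) <= 0))
    }
  })
  expect_error(make_schedule(alpha_start = 0.5, alpha_end = 0.9), "alpha_end")
  expect_error(make_schedule(T = 0), "T must")
})

test_that("forward steps have the stated conditional moments", {
  s <- make_schedule(T = 3, alpha_start = 1, alpha_end = 1)
  x0 <- diffusion_state(matrix(0.5, 4, 4), 0L)
  withr::with_seed(1, {
    st <- forward_step(x0, s)
    expect_equal(st$x, matrix(0.5, 4, 4))  # alpha = 1: noiseless
    expect_equal(st$t, 1L)
  })
  # Monte-Carlo conditional variance matches 1 - alpha_t within 3 SE
  s2 <- make_schedule(T = 1, alpha_start = 0.7, alpha_end = 0.7)
  withr::with_seed(2, {
    draws <- replicate(10000, forward_step(diffusion_state(0.3, 0L), s2)$x)
  })
  resid <- draws - 0.7 * 0.3
  expect_equal(mean(resid), 0, tolerance = 3 * sqrt(0.3) / 100)
  v_hat <- var(resid)
  se_v <- 0.3 * sqrt(2 / 9999)
  expect_lt(abs(v_hat - 0.3), 3 * se_v)
  expect_error(forward_step(diffusion_state(0.1, 1L), s2), "final step")
})

test_that("forward marginal matches the composed chain in distribution", {
  alphas <- c(0.9, 0.8, 0.7)
  s <- make_schedule(T = 3, alpha_start = 0.9, alpha_end = 0.7)
  expect_equal(s$alpha, alphas)
  x0 <- array(runif(16, -1, 1), dim = c(4, 4, 1))
  n <- 4000
  withr::with_seed(3, {
    marg <- replicate(n, forward_marginal(x0, 3, s)$x[1, 1, 1])
    chain <- replicate(n, {
      st <- diffusion_state(x0, 0L)
      for (i in 1:3) st <- forward_step(st, s)
      st$x[1, 1, 1]
    })
  })
  se <- sqrt(var(marg) / n + var(chain) / n)
  expect_lt(abs(mean(marg) - mean(chain)), 3 * se)
  expect_lt(abs(mean(marg) - s$m[3] * x0[1, 1, 1]), 3 * sqrt(var(marg) / n))
  vr <- var(marg)
  expect_lt(abs(vr - s$v[3]), 3 * s$v[3] * sqrt(2 / (n - 1)))
  # noiseless chain returns x0 exactly
  sid <- make_schedule(T = 4, alpha_start = 1, alpha_end = 1)
  expect_equal(forward_marginal(x0, 4, sid)$x, x0)
  expect_error(forward_marginal(x0, 5, s), "1..T")
})

test_that("gaussian KL matches its closed form and is nonnegative", {
  expect_equal(gaussian_kl(0, 1, 0, 1), 0)
  expect_equal(gaussian_kl(0, 1, 1, 1), 0.5)
  withr::with_seed(4, {
    for (rep in 1:20) {
      expect_gte(gaussian_kl(rnorm(1), runif(1, 0.1, 2),
                             rnorm(1), runif(1, 0.1, 2)), 0)
    }
  })
  expect_error(gaussian_kl(0, 0, 0, 1), "positive")
})

test_that("reverse step evaluates the printed denoising relation exactly", {
  s <- make_schedule(T = 2, alpha_start = 0.9, alpha_end = 0.9)
  # direct numeric evaluation: (1/0.9) * (1 - (0.1/sqrt(1-0.81)) * 0.5)
  expect_equal(reverse_step(1.0, 1, 0.5, s),
               (1 / 0.9) * (1 - (0.1 / sqrt(1 - 0.81)) * 0.5),
               tolerance = 1e-12)
  expect_equal(reverse_step(1.0, 1, 0.5, s), 0.98366, tolerance = 1e-5)
  # zero predicted noise: x / alpha
  x <- matrix(runif(9), 3, 3)
  expect_equal(reverse_step(x, 2, matrix(0, 3, 3), s), x / 0.9)
  expect_equal(dim(reverse_step(x, 1, x, s)), dim(x))
})

test_that("reverse step is the exact algebraic inverse of its forward relation", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      a <- runif(1, 0.5, 0.99)
      s <- make_schedule(T = 1, alpha_start = a, alpha_end = a)
      xhat <- array(rnorm(8), dim = c(2, 2, 2))
      eps <- array(rnorm(8), dim = c(2, 2, 2))
      x_t <- a * xhat + (1 - a) / sqrt(1 - a^2) * eps
      expect_equal(reverse_step(x_t, 1, eps, s), xhat, tolerance = 1e-10)
    }
  })
})

test_that("vlb loss is zero for a perfect 1-step prediction and penalizes error", {
  # under the sqrt-parameterized (ddpm) convention, predicting the exact
  # injected noise makes the reverse mean recover x0 exactly; the literal
  # printed relation is not self-inverse, which is why the flag exists
  s <- make_schedule(T = 1, convention = "ddpm", alpha_start = 0.9,
                     alpha_end = 0.9)
  x0 <- array(0.2, dim = c(2, 2, 1, 1))
  eps <- array(rnorm(4), dim = dim(x0))
  xt <- s$m[1] * x0 + sqrt(s$v[1]) * eps
  mup <- reverse_step(xt, 1, eps, s)
  expect_equal(mup, x0, tolerance = 1e-12)
  # evaluating the loss at eps_hat = eps vs a perturbed prediction:
  # the data-dependent part strictly grows with prediction error
  s2 <- make_schedule(T = 3, convention = "ddpm", alpha_start = 0.95,
                      alpha_end = 0.85)
  term_at <- function(delta) {
    xt2 <- s2$m[2] * x0 + sqrt(s2$v[2]) * eps
    mu_p <- reverse_step(xt2, 2, eps + delta, s2)
    pm <- leafpad:::posterior_moments(x0, xt2, 2, s2)
    sum((pm$mu - mu_p)^2) / (2 * pm$var)
  }
  expect_lt(term_at(0), term_at(0.05))
  expect_lt(term_at(0.05), term_at(0.1))
})

test_that("vlb loss is finite on random inputs and schedules", {
  dn <- denoiser_init(channels = 1L, width = 4L, body = 1L, seed = 1)
  s <- make_schedule(T = 8, alpha_start = 0.99, alpha_end = 0.9)
  withr::with_seed(6, {
    for (rep in 1:5) {
      x0 <- array(runif(32, -1, 1), dim = c(4, 4, 1, 2))
      l <- vlb_loss(x0, dn, s)
      expect_true(is.finite(l))
    }
  })
})

test_that("vlb gradients match finite differences", {
  sched <- make_schedule(T = 5, alpha_start = 0.99, alpha_end = 0.9)
  dn <- denoiser_init(channels = 1L, width = 5L, body = 1L, seed = 6)
  skel <- unclass(dn)[c("conv_in", "temb", "body", "conv_out")]
  withr::with_seed(7, {
    x0 <- array(rnorm(36 * 2), dim = c(6, 6, 1, 2))
    epsn <- array(rnorm(length(x0)), dim = dim(x0))
  })
  tt <- c(1L, 4L)
  lg <- vlb_loss(x0, dn, sched, t = tt, eps = epsn, return_grads = TRUE)
  gflat <- leafpad:::tree_flatten(lg$grads)
  idx <- withr::with_seed(8, sample(length(gflat), 40))
  num <- numeric_grad(function(p) vlb_loss(x0, p, sched, t = tt, eps = epsn),
                      skel, idx)
  rel <- abs(num - gflat[idx]) / pmax(abs(num) + abs(gflat[idx]), 1e-5)
  expect_lt(max(rel), 1e-4)
})

test_that("training the denoiser decreases the fixed-eval VLB", {
  withr::with_seed(30, {
    x0s <- lapply(1:8, function(i) array(tanh(rnorm(64, sd = 0.5)), dim = c(8, 8, 1)))
  })
  sched <- make_schedule(T = 8, alpha_start = 0.99, alpha_end = 0.9)
  dn <- denoiser_init(channels = 1L, width = 8L, body = 1L, seed = 2)
  tr <- train_denoiser(x0s, dn, sched, epochs = 10, batch = 4, lr = 2e-3, seed = 3)
  expect_lt(tr$history[10], tr$history[1])
})

test_that("diffusion sampling is deterministic and uses T denoiser evaluations", {
  dn <- denoiser_init(channels = 1L, width = 4L, body = 1L, seed = 4)
  s <- make_schedule(T = 6, alpha_start = 0.99, alpha_end = 0.9)
  a <- sample_diffusion(dn, s, c(6, 6, 1), seed = 9)
  b <- sample_diffusion(dn, s, c(6, 6, 1), seed = 9)
  expect_identical(a, b)
  expect_equal(attr(a, "n_evals"), 6L)
  expect_true(all(a >= -1 & a <= 1))
  # all-alpha-1 schedule with a zero denoiser returns the initial draw
  sid <- make_schedule(T = 3, alpha_start = 1, alpha_end = 1)
  dz <- dn
  dz$conv_out$W[] <- 0; dz$conv_out$b[] <- 0
  smp <- sample_diffusion(dz, sid, c(4, 4, 1), seed = 10)
  init <- withr::with_seed(10, array(rnorm(16), dim = c(4, 4, 1, 1)))
  expect_equal(unclass(smp), pmin(pmax(init, -1), 1), ignore_attr = TRUE)
})
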