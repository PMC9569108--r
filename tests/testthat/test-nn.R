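# Backpropagation is validated against central differences; these checks
# are the correctness oracle for every gradient-trained model in the
# package.

rel_err <- function(a, b) {
  max(abs(as.numeric(a) - as.numeric(b))) /
    max(1e-8, max(abs(as.numeric(b))))
}

grad_check <- function(analytic, params, f, tol = 1e-5) {
  ng <- descvae:::numeric_grad(f, params)
  fa <- descvae:::.flatten_params(analytic)
  fn <- descvae:::.flatten_params(ng)
  expect_setequal(names(fa), names(fn))
  for (nm in names(fn)) expect_lt(rel_err(fa[[nm]], fn[[nm]]), tol)
}

test_that("GRU backward matches numerical gradients", {
  set.seed(1)
  n <- 3; d <- 4; H <- 5; T_len <- 6
  p <- descvae:::gru_init(d, H)
  X <- lapply(seq_len(T_len), function(t) matrix(rnorm(n * d), n, d))
  h0 <- matrix(rnorm(n * H), n, H)
  # scalar objective: weighted sum of all hidden states
  W_obj <- lapply(seq_len(T_len), function(t) matrix(rnorm(n * H), n, H))
  fwd <- descvae:::gru_forward(X, p, h0)
  loss_of <- function(pp) {
    fw <- descvae:::gru_forward(X, pp, h0)
    sum(vapply(seq_len(T_len),
               function(t) sum(fw$H_list[[t]] * W_obj[[t]]), numeric(1)))
  }
  bg <- descvae:::gru_backward(X, p, fwd, W_obj)
  grad_check(bg$grads, p, loss_of)
})

test_that("conv1d backward matches numerical gradients (params and input)", {
  set.seed(2)
  n <- 2; T_len <- 7; c_in <- 3; c_out <- 4; k <- 5
  p <- descvae:::conv1d_init(k, c_in, c_out)
  X <- array(rnorm(n * T_len * c_in), dim = c(n, T_len, c_in))
  W_obj <- array(rnorm(n * T_len * c_out), dim = c(n, T_len, c_out))
  fwd <- descvae:::conv1d_forward(X, p)
  bg <- descvae:::conv1d_backward(X, p, fwd, W_obj)
  grad_check(bg$grads, p, function(pp) {
    sum(descvae:::conv1d_forward(X, pp)$Y * W_obj)
  })
  # input gradient via the same oracle
  ngX <- array(0, dim = dim(X))
  eps <- 1e-5
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- X[i] + eps
    Xm <- X; Xm[i] <- X[i] - eps
    ngX[i] <- (sum(descvae:::conv1d_forward(Xp, p)$Y * W_obj) -
                 sum(descvae:::conv1d_forward(Xm, p)$Y * W_obj)) / (2 * eps)
  }
  expect_lt(rel_err(bg$dX, ngX), 1e-5)
})

test_that("full VAE gradients are exact for both variants", {
  set.seed(3)
  corpus <- c("CCO", "CC(C)N", "OCC", "NCC(O)C")
  v <- build_vocabulary(corpus)
  ids <- tokenize(corpus, v)
  eps <- matrix(rnorm(4 * 3), 4, 3)
  tgt <- matrix(rnorm(8), 4, 2)
  w <- char_weights(corpus, v)
  for (variant in c("pvae", "cvae")) {
    cfg <- vae_config(variant, latent_dim = 3, hidden_dim = 4,
                      conv_channels = c(3L, 3L), conv_kernels = c(3L, 3L),
                      predictor_hidden = c(4L, 4L, 4L), epochs = 1,
                      seed = 1)
    p <- descvae:::.vae_init_params(cfg, v, 2L)
    res <- descvae:::.vae_batch_grad(p, cfg, ids, v, eps, w, tgt,
                                     beta_eff = 0.7)
    grad_check(res$grads, p, function(pp) {
      descvae:::.vae_batch_grad(pp, cfg, ids, v, eps, w, tgt, 0.7)$total
    }, tol = 1e-4)
  }
})

test_that("Adam reduces a convex objective", {
  set.seed(4)
  p <- list(layer = descvae:::dense_init(3, 1))
  X <- matrix(rnorm(60), 20, 3)
  y <- X %*% c(1, -2, 0.5)
  opt <- descvae:::adam_init(p)
  loss0 <- mean((descvae:::dense_forward(X, p$layer) - y)^2)
  for (i in 1:300) {
    pred <- descvae:::dense_forward(X, p$layer)
    d <- 2 * (pred - y) / length(y)
    g <- list(layer = descvae:::dense_backward(X, p$layer, d)$grads)
    st <- descvae:::adam_step(p, g, opt, lr = 0.05)
    p <- st$params; opt <- st$state
  }
  loss1 <- mean((descvae:::dense_forward(X, p$layer) - y)^2)
  expect_lt(loss1, loss0 / 100)
})
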