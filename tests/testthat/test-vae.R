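test_that("vocabulary construction is deterministic and validates length", {
  corpus <- small_corpus()
  v1 <- build_vocabulary(corpus)
  v2 <- build_vocabulary(corpus)
  expect_identical(v1, v2)
  expect_true(all(c("<pad>", "<s>", "</s>") %in% v1$tokens))
  expect_equal(unname(v1$token_to_index[v1$tokens]),
               seq_along(v1$tokens))
  expect_error(build_vocabulary(c("CCO"), max_length = 4), "too long")
  # two-character atoms are single tokens
  vcl <- build_vocabulary("CCl")
  expect_true("Cl" %in% vcl$tokens)
  expect_false("l" %in% vcl$tokens)
})

test_that("tokenize/detokenize round-trips the corpus", {
  corpus <- small_corpus(50, seed = 13)
  v <- build_vocabulary(corpus)
  ids <- tokenize(corpus, v)
  expect_equal(dim(ids), c(length(corpus), v$max_length))
  expect_identical(detokenize(ids, v), corpus)
  # empty string is start+end+pads
  v2 <- build_vocabulary("CCO", max_length = 6)
  row <- tokenize("", v2)[1, ]
  expect_identical(row, c(v2$bos, v2$eos, rep(v2$pad, 4)))
  expect_identical(detokenize(row, v2), "")
  expect_error(tokenize("CBr", v2), "unknown token")
})

test_that("character weights follow inverse prevalence and conserve mass", {
  v <- build_vocabulary("CCO")
  w <- char_weights("CCO", v)
  expect_equal(unname(w["C"]), 0.75)
  expect_equal(unname(w["O"]), 1.5)
  # uniform corpus gives all-ones over seen tokens
  vu <- build_vocabulary("CON")
  wu <- char_weights("CON", vu)
  expect_equal(unname(wu[c("C", "O", "N")]), c(1, 1, 1))
  # rarer token always weighted above a more frequent one
  corpus <- small_corpus()
  vv <- build_vocabulary(corpus)
  ww <- char_weights(corpus, vv)
  cnt <- table(unlist(descvae:::smiles_tokens(corpus)))
  cnt <- sort(cnt, decreasing = TRUE)
  expect_true(all(diff(ww[names(cnt)]) >= 0))
  # weighted token mass is conserved: sum w_c * n_c = N
  expect_equal(sum(ww[names(cnt)] * as.numeric(cnt)), sum(cnt))
})

test_that("KL to prior matches the closed form and a Monte-Carlo estimate", {
  expect_equal(kl_to_prior(rep(0, 8), rep(0, 8)), 0)
  expect_equal(kl_to_prior(2, 0), 2)
  expect_equal(kl_to_prior(0, log(4)), 0.5 * (4 - log(4) - 1))
  expect_error(kl_to_prior(c(1, NaN), c(0, 0)), "finite")
  expect_error(kl_to_prior(1, c(0, 0)), "lengths")
  # Monte-Carlo cross-check: E_q[log q - log p] under q = N(mu, sigma^2)
  set.seed(20)
  for (rep_i in 1:5) {
    mu <- rnorm(4, 0, 1)
    lv <- rnorm(4, 0, 0.5)
    z <- sweep(sweep(matrix(rnorm(4e5 * 4), ncol = 4), 2,
                     exp(lv / 2), "*"), 2, mu, "+")
    logq <- sapply(1:4, function(j) dnorm(z[, j], mu[j], exp(lv[j] / 2),
                                          log = TRUE))
    logp <- sapply(1:4, function(j) dnorm(z[, j], log = TRUE))
    mc <- mean(rowSums(logq - logp))
    expect_lt(abs(mc - kl_to_prior(mu, lv)), 1e-2)
    expect_gte(kl_to_prior(mu, lv), 0)
  }
})

test_that("vae_loss components behave as the ablation identities require", {
  set.seed(21)
  n <- 3; T_len <- 4; V <- 5
  tgt <- matrix(sample(2:V, n * T_len, replace = TRUE), n, T_len)
  tgt[1, 4] <- 1L  # one pad position
  # logits concentrated on the correct token -> zero reconstruction
  logits <- array(-50, dim = c(n, T_len, V))
  for (i in seq_len(n)) for (t in seq_len(T_len)) {
    logits[i, t, tgt[i, t]] <- 50
  }
  mu0 <- matrix(0, n, 2); lv0 <- matrix(0, n, 2)
  l0 <- vae_loss(logits, tgt, mu0, lv0)
  expect_equal(l0$total, 0, tolerance = 1e-8)
  # random logits: uniform weights equal unweighted; lambda 0 removes pred
  logits <- array(rnorm(n * T_len * V), dim = c(n, T_len, V))
  mu <- matrix(rnorm(n * 2), n, 2); lv <- matrix(rnorm(n * 2), n, 2)
  pred <- matrix(rnorm(n * 2), n, 2); ptgt <- matrix(rnorm(n * 2), n, 2)
  lu <- vae_loss(logits, tgt, mu, lv, weights = NULL, beta = 1)
  lw <- vae_loss(logits, tgt, mu, lv, weights = rep(1, V), beta = 1)
  expect_equal(lw$total, lu$total)
  lp0 <- vae_loss(logits, tgt, mu, lv, pred_out = pred, pred_targets = ptgt,
                  lambda_pred = 0)
  expect_equal(lp0$total, lu$total)
  expect_true(all(lu$components >= 0))
  # total is monotone in beta when kl > 0
  lb2 <- vae_loss(logits, tgt, mu, lv, beta = 2)
  expect_gt(lb2$total, lu$total)
  expect_error(vae_loss(logits, tgt[, 1:2], mu, lv), "shape")
  expect_error(vae_loss(logits, tgt, mu, lv, pred_out = pred), "together")
})

test_that("training learns, is seed-reproducible, and records history", {
  corpus <- small_corpus(24, seed = 31)
  cfg <- vae_config("pvae", latent_dim = 8, hidden_dim = 24, epochs = 25,
                    beta = 0.05, lambda_pred = 0, lr = 3e-3, seed = 7)
  m1 <- train_vae(cfg, corpus)
  expect_s3_class(m1, "smiles_vae")
  expect_equal(nrow(m1$history), 25L)
  expect_true(all(is.finite(as.matrix(m1$history))))
  expect_lt(tail(m1$history$reconstruction, 1), m1$history$reconstruction[1])
  m2 <- train_vae(cfg, corpus)
  expect_identical(m1$history, m2$history)
  # joint training drives the predictor component down
  desc <- compute_descriptors(mol_dataset_from_smiles(corpus), "MolLogP")
  cfgj <- vae_config("pvae", latent_dim = 8, hidden_dim = 24, epochs = 40,
                     beta = 0.05, lambda_pred = 5, lr = 3e-3, seed = 7)
  mj <- train_vae(cfgj, corpus, descriptor_table = desc)
  expect_equal(mj$descriptor_names, "MolLogP")
  expect_lt(tail(mj$history$predictor, 1), mj$history$predictor[1])
  # coverage gap is a validation error
  expect_error(train_vae(cfgj, corpus, descriptor_table = desc[1:3, ,
                                                               drop = FALSE]),
               "cover")
})

test_that("cvae variant trains and enforces its predictor depth", {
  corpus <- small_corpus(16, seed = 33)
  cfg <- vae_config("cvae", latent_dim = 6, hidden_dim = 16,
                    conv_channels = c(8L, 8L), conv_kernels = c(3L, 3L),
                    epochs = 10, beta = 0.05, lambda_pred = 0, lr = 3e-3,
                    seed = 2)
  m <- train_vae(cfg, corpus)
  expect_lt(tail(m$history$reconstruction, 1), m$history$reconstruction[1])
  expect_error(vae_config("cvae", predictor_hidden = c(8L, 8L)),
               "3 hidden layers")
})

test_that("embeddings expose posteriors with the contracted modes", {
  corpus <- small_corpus(20, seed = 35)
  cfg <- vae_config("pvae", latent_dim = 8, hidden_dim = 16, epochs = 5,
                    seed = 3)
  m <- train_vae(cfg, corpus)
  e1 <- embed_molecules(m, corpus, mode = "mean")
  e2 <- embed_molecules(m, corpus, mode = "mean")
  expect_identical(e1$vectors, e2$vectors)
  expect_identical(e1$vectors, e1$posterior_means)
  expect_equal(ncol(e1$vectors), 8L)
  expect_true(all(is.finite(e1$vectors)))
  s1 <- embed_molecules(m, corpus, mode = "sample", seed = 5)
  s2 <- embed_molecules(m, corpus, mode = "sample", seed = 5)
  s3 <- embed_molecules(m, corpus, mode = "sample", seed = 6)
  expect_identical(s1$vectors, s2$vectors)
  expect_false(identical(s1$vectors, s3$vectors))
  expect_error(embed_molecules(m, "C[Si]"), "unknown token")
  # default latent width matches the full-scale setting
  expect_equal(vae_config()$latent_dim, 196L)
})

test_that("reconstruction accuracy contract: empty input, untrained chance", {
  corpus <- small_corpus(20, seed = 35)
  cfg <- vae_config("pvae", latent_dim = 8, hidden_dim = 16, epochs = 1,
                    seed = 4)
  m <- train_vae(cfg, corpus)
  expect_error(reconstruction_accuracy(m, character(0)), "empty")
  acc <- reconstruction_accuracy(m, corpus)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  expect_lt(acc, 0.05)  # one epoch is chance level for exact string match
})

test_that("model serialization round-trips embeddings exactly", {
  corpus <- small_corpus(16, seed = 33)
  desc <- compute_descriptors(mol_dataset_from_smiles(corpus), "MolWt")
  cfg <- vae_config("pvae", latent_dim = 6, hidden_dim = 12, epochs = 4,
                    lambda_pred = 1, seed = 8)
  m <- train_vae(cfg, corpus, descriptor_table = desc)
  d <- tempfile("vae_model_")
  save_vae(m, d)
  expect_true(all(file.exists(file.path(d, c("config.yaml", "vocab.json",
                                             "standardization.json",
                                             "weights.rds")))))
  m2 <- load_vae(d)
  expect_identical(embed_molecules(m2, corpus)$vectors,
                   embed_molecules(m, corpus)$vectors)
  expect_identical(m2$descriptor_names, m$descriptor_names)
})
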