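test_that("bootstrap comparison is calibrated, symmetric, reproducible", {
  set.seed(50)
  n <- 200
  y <- rnorm(n)
  fold <- rep(1:10, each = 20)
  good <- y + rnorm(n, 0, 0.2)
  bad <- sample(y)
  # identical candidates: zero strict exceedance, not significant
  same <- bootstrap_compare(good, good, y, fold, "r2", n_trials = 300,
                            seed = 1)
  expect_equal(same$proportion, 0)
  expect_false(same$significant)
  expect_equal(same$direction, "none")
  # planted gap: near-certain exceedance
  gap <- bootstrap_compare(good, bad, y, fold, "r2", n_trials = 500,
                           seed = 1)
  expect_true(gap$significant)
  expect_gt(gap$proportion, 0.99)
  expect_equal(gap$direction, "a")
  # symmetry: swapping candidates swaps direction, preserves proportion
  swp <- bootstrap_compare(bad, good, y, fold, "r2", n_trials = 500,
                           seed = 1)
  expect_equal(swp$proportion, gap$proportion)
  expect_equal(swp$direction, "b")
  # determinism
  rep2 <- bootstrap_compare(good, bad, y, fold, "r2", n_trials = 500,
                            seed = 1)
  expect_equal(rep2$proportion, gap$proportion)
  # accuracy metric on binary labels
  yb <- as.integer(y > 0)
  pa <- ifelse(runif(n) < 0.9, yb, 1 - yb)
  pb <- sample(yb)
  ba <- bootstrap_compare(pa, pb, yb, fold, "accuracy", n_trials = 300,
                          seed = 2)
  expect_true(ba$significant)
  expect_error(bootstrap_compare(good, bad, y, fold, "accuracy"),
               "binary")
})

test_that("dataset-to-prior distance is the mean molecule-level KL", {
  emb <- blob_embedding()
  kl <- descvae:::.kl_rows(emb$posterior_means, emb$posterior_logvars)
  expect_equal(mean(kl),
               mean(vapply(seq_len(nrow(emb$vectors)), function(i) {
                 kl_to_prior(emb$posterior_means[i, ],
                             emb$posterior_logvars[i, ])
               }, numeric(1))))
  # single molecule with mu = (2, 0, ...), unit variances -> 2
  expect_equal(kl_to_prior(c(2, rep(0, 7)), rep(0, 8)), 2)
})

test_that("linear probe reads out embedded information at the right scale", {
  set.seed(51)
  n <- 200
  target <- rnorm(n, 5, 3)
  z <- (target - mean(target)) / sd(target)
  # target embedded verbatim in the first coordinate -> near-zero RMSE
  emb <- cbind(z, matrix(rnorm(n * 7), n, 7))
  probe <- linear_probe(emb, target, seed = 1)
  expect_lt(probe$rmse_mean, 1e-6)
  # independent Gaussian embeddings -> RMSE near 1 on standardized scale
  null_emb <- matrix(rnorm(n * 8), n, 8)
  null_probe <- linear_probe(null_emb, target, seed = 1)
  expect_gt(null_probe$rmse_mean, 0.85)
  expect_lt(null_probe$rmse_mean, 1.25)
  expect_equal(null_probe$rmse_raw_mean, null_probe$rmse_mean * sd(target))
  # invariance under orthogonal rotation of the embedding space
  qr_dec <- qr(matrix(rnorm(64), 8, 8))
  Q <- qr.Q(qr_dec)
  rot_probe <- linear_probe(emb %*% Q, target, seed = 1)
  expect_equal(rot_probe$rmse_mean, probe$rmse_mean, tolerance = 1e-6)
  expect_error(linear_probe(emb, rep(1, n)), "constant")
})

test_that("cluster diagnostics recover planted structure", {
  emb <- blob_embedding(n_per = 30, k = 5)
  n <- nrow(emb$vectors)
  blob_id <- rep(1:5, each = 30)
  set.seed(52)
  y <- rnorm(n)
  preds <- y + rnorm(n, 0, ifelse(blob_id == 5, 1.5, 0.1))
  diag5 <- cluster_error_analysis(emb, preds, y, k = 5, seed = 3)
  expect_equal(sum(diag5$clusters$size), n)
  expect_true(all(diag5$clusters$kl_distance >= 0))
  # the far, noisy blob is one cluster with max distance and max RMSE
  worst <- which.max(diag5$clusters$kl_distance)
  expect_equal(which.max(diag5$clusters$rmse), worst)
  far_members <- diag5$assignment[blob_id == 5]
  expect_equal(length(unique(far_members)), 1L)
  # k = 1: single cluster RMSE equals overall RMSE
  diag1 <- cluster_error_analysis(emb, preds, y, k = 1, seed = 3)
  expect_equal(diag1$clusters$rmse, metric_rmse(y, preds))
  # seeded determinism
  diag5b <- cluster_error_analysis(emb, preds, y, k = 5, seed = 3)
  expect_identical(diag5$assignment, diag5b$assignment)
  expect_error(cluster_error_analysis(emb, preds, y, k = n + 1), "exceeds")
})

test_that("PCA projection preserves what it must", {
  # data exactly on a line: first component explains everything
  t_line <- seq(-2, 2, length.out = 40)
  line <- cbind(3 * t_line, -t_line, 0.5 * t_line)
  p <- pca_project(line, 2)
  expect_equal(p$explained_variance[1], 1)
  # 2-d data, 2 components: pairwise distances preserved
  set.seed(53)
  X2 <- matrix(rnorm(60), 30, 2)
  p2 <- pca_project(X2, 2)
  expect_equal(as.numeric(dist(p2$scores)), as.numeric(dist(X2)))
  expect_lte(sum(p2$explained_variance), 1 + 1e-12)
  expect_true(all(diff(p2$explained_variance) <= 0))
  expect_error(pca_project(matrix(1, 10, 3), 2), "degenerate")
})
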