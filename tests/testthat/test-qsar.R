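test_that("regression metrics match hand-computed values exactly", {
  y <- c(1, 2, 3)
  expect_equal(metric_r2(y, y), 1)
  expect_equal(metric_r2(y, rep(mean(y), 3)), 0)
  expect_equal(metric_r2(y, c(1, 2, 4)), 0.5)
  expect_error(metric_r2(rep(1, 3), y), "constant")
  expect_equal(metric_rmse(y, y), 0)
  expect_equal(metric_rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  # homogeneity under common scaling
  set.seed(40)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(metric_rmse(3 * a, 3 * b), 3 * metric_rmse(a, b))
  expect_error(metric_rmse(a, b[1:5]), "mismatch")
  # r2 never exceeds 1
  expect_lte(metric_r2(a, b), 1)
})

test_that("classification metrics match confusion-table arithmetic", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)  # TP=2 FP=1 FN=1 TN=6
  m <- metric_accuracy_f1(y, pred)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_equal(unname(metric_accuracy_f1(y, y)), c(1, 1))
  expect_equal(unname(metric_accuracy_f1(y, rep(0, 10))["f1"]), 0)
  expect_error(metric_accuracy_f1(y, pred * 2), "binary")
})

test_that("cross-validation partitions cleanly and is leakage-free", {
  set.seed(41)
  n <- 100; d <- 5
  X <- matrix(rnorm(n * d), n, d)
  w <- rnorm(d)
  y <- drop(X %*% w)
  cv <- run_cv(model_spec("linear", "regression"), X, y, seed = 2)
  # exact partition: every molecule in exactly one fold, sizes differ <= 1
  expect_equal(sort(unique(cv$fold_assignment)), 1:10)
  sizes <- table(cv$fold_assignment)
  expect_lte(max(sizes) - min(sizes), 1)
  # realizable hypothesis: per-fold R2 = 1
  expect_true(all(abs(cv$per_fold_metrics$r2 - 1) < 1e-9))
  # determinism
  cv2 <- run_cv(model_spec("linear", "regression"), X, y, seed = 2)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_identical(cv$predictions, cv2$predictions)
  # aggregate mean equals arithmetic mean of folds
  expect_equal(cv$aggregate$mean[cv$aggregate$metric == "r2"],
               mean(cv$per_fold_metrics$r2), tolerance = 1e-12)
  # leakage: perturbing one held-out label only changes its own fold's
  # model inputs; all other folds' predictions are bit-identical
  y_pert <- y
  victim <- which(cv$fold_assignment == 1)[1]
  y_pert[victim] <- y_pert[victim] + 100
  cv_p <- run_cv(model_spec("linear", "regression"), X, y_pert, seed = 2)
  other <- cv$fold_assignment == 1
  expect_identical(cv_p$predictions[other], cv$predictions[other])
  expect_false(identical(cv_p$predictions[!other], cv$predictions[!other]))
  # validation errors
  expect_error(run_cv(model_spec("linear"), X[1:5, ], y[1:5]), "n_folds")
  Xbad <- X; Xbad[1] <- NA
  expect_error(run_cv(model_spec("linear"), Xbad, y), "non-finite")
})

test_that("classification CV is stratified and returns probabilities", {
  set.seed(42)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(drop(X %*% c(2, -1, 0.5, 1)) + rnorm(n, 0, 0.3) > 0)
  cv <- run_cv(model_spec("linear", "classification"), X, y, seed = 3)
  # stratification: every fold carries both classes
  tab <- table(cv$fold_assignment, y)
  expect_true(all(tab > 0))
  expect_true(all(cv$predictions >= 0 & cv$predictions <= 1))
  expect_true(all(cv$class_predictions %in% c(0, 1)))
  expect_gt(cv$aggregate$mean[cv$aggregate$metric == "accuracy"], 0.8)
})

test_that("feature permutation leaves linear-family predictions invariant", {
  set.seed(43)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(80, 0, 0.1)
  perm <- sample(6)
  cv_a <- run_cv(model_spec("linear", "regression"), X, y, seed = 4)
  cv_b <- run_cv(model_spec("linear", "regression"), X[, perm], y, seed = 4)
  expect_equal(cv_a$predictions, cv_b$predictions, tolerance = 1e-9)
})

test_that("neural families have the capacity for a planted linear signal", {
  set.seed(44)
  n <- 200; d <- 8
  X <- matrix(rnorm(n * d), n, d)
  y <- drop(X %*% rnorm(d))
  wins_mlp <- 0L
  wins_res <- 0L
  for (s in 1:3) {
    cv_m <- run_cv(model_spec("mlp", "regression", epochs = 150, seed = s),
                   X, y, n_folds = 5, seed = s)
    cv_r <- run_cv(model_spec("resnet1d", "regression", epochs = 60,
                              blocks = 2L, channels = 16L, seed = s),
                   X, y, n_folds = 5, seed = s)
    if (cv_m$aggregate$mean[cv_m$aggregate$metric == "r2"] >= 0.8) {
      wins_mlp <- wins_mlp + 1L
    }
    if (cv_r$aggregate$mean[cv_r$aggregate$metric == "r2"] >= 0.8) {
      wins_res <- wins_res + 1L
    }
  }
  expect_gte(wins_mlp, 2L)
  expect_gte(wins_res, 2L)
})

test_that("circular fingerprints are deterministic structure signatures", {
  ds <- mol_dataset_from_smiles(c("CCO", "CCO", "CCCCCC"))
  fp <- build_baseline_fingerprint(ds, n_bits = 1024L)
  expect_equal(dim(fp), c(3L, 1024L))
  expect_true(all(fp %in% c(0, 1)))
  expect_identical(fp[1, ], fp[2, ])          # identical molecules
  expect_gt(sum(fp[1, ] != fp[3, ]), 0)       # ethanol vs hexane differ
  expect_true(all(rowSums(fp) >= 1))
})
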