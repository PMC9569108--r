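test_that("variance filter keeps strictly above-threshold columns", {
  tab <- data.frame(const = rep(1, 10),
                    binary = rep(c(0, 1), 5),
                    wide = seq(0, 90, by = 10))
  out <- variance_filter(tab, 0.5)
  # balanced binary has variance 0.25/0.9*... sample var = 0.2777 < 0.5
  expect_identical(names(out), "wide")
  expect_setequal(attr(out, "removed_low_variance"), c("const", "binary"))
  expect_error(variance_filter(tab[, 0]), "no columns")
})

test_that("correlation ranking is ordered by |r| with exact values", {
  y <- c(1, 3, 2, 5, 4)
  tab <- data.frame(perfect = 2 * y + 1, negated = -y,
                    noise = c(0.3, -0.2, 0.9, 0.1, -0.5))
  rk <- rank_by_target_correlation(tab, y)
  expect_equal(rk$descriptor[1:2], c("negated", "perfect"))  # alphabetical tie
  expect_equal(rk$pearson_r[rk$descriptor == "perfect"], 1)
  expect_equal(rk$pearson_r[rk$descriptor == "negated"], -1)
  expect_true(all(abs(rk$pearson_r) <= 1))
  # hand-computed 3-point Pearson
  rk3 <- rank_by_target_correlation(data.frame(d = c(1, 2, 3)), c(1, 3, 2))
  expect_equal(rk3$pearson_r, 0.5)
  # affine invariance
  rk_scaled <- rank_by_target_correlation(tab * 3 + 7, y * 2 - 1)
  expect_equal(rk_scaled$pearson_r, rk$pearson_r)
  # constant column excluded with a warning
  expect_warning(rank_by_target_correlation(cbind(tab, flat = 1), y),
                 "constant")
  expect_error(rank_by_target_correlation(tab, rep(1, 5)), "constant")
})

test_that("greedy pruning keeps the more task-correlated of a pair", {
  set.seed(8)
  a <- rnorm(200)
  y <- a + rnorm(200, 0, 0.3)
  tab <- data.frame(a = a, b = a + rnorm(200, 0, 0.05),
                    c = rnorm(200))
  rk <- rank_by_target_correlation(tab, y)
  res <- prune_intercorrelated(rk, tab, r_max = 0.9)
  # exactly one of the near-duplicate pair survives, and it is the member
  # ranked higher by |target correlation|
  expect_equal(sum(c("a", "b") %in% res$selected), 1L)
  higher <- rk$descriptor[rk$descriptor %in% c("a", "b")][1]
  lower <- setdiff(c("a", "b"), higher)
  expect_true(higher %in% res$selected)
  expect_equal(res$removed_intercorrelated$dropped, lower)
  expect_equal(res$removed_intercorrelated$kept, higher)
  expect_gt(abs(res$removed_intercorrelated$r), 0.9)
  # brute-force all-pairs check on survivors
  surv <- as.matrix(tab[res$selected])
  cors <- cor(surv)
  expect_true(all(abs(cors[upper.tri(cors)]) <= 0.9))
  # independent columns all survive
  set.seed(9)
  ind <- data.frame(x = rnorm(100), y2 = rnorm(100), z = rnorm(100))
  rk2 <- rank_by_target_correlation(ind, rnorm(100))
  expect_length(prune_intercorrelated(rk2, ind)$selected, 3L)
})

test_that("top-k selection respects ranking order and validates k", {
  set.seed(10)
  tab <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  y <- tab$a + 0.5 * tab$b + rnorm(50, 0, 0.2)
  res <- select_descriptors(tab, y, var_threshold = 0, k = 3)
  expect_equal(res$top_k[1], "a")
  expect_equal(select_top_k(res, 1), "a")
  expect_error(select_top_k(res, 0), ">= 1")
})

test_that("labelled-subset mask restricts the correlation computation", {
  set.seed(11)
  d <- rnorm(100)
  y <- d + rnorm(100, 0, 0.1)
  y[51:100] <- 0  # unlabeled half encoded as placeholder
  mask <- c(rep(TRUE, 50), rep(FALSE, 50))
  rk <- rank_by_target_correlation(data.frame(d = d), y, mask = mask)
  expect_equal(rk$pearson_r, cor(d[1:50], y[1:50]))
})

test_that("noisy descriptor attenuates correlation by the closed form", {
  set.seed(12)
  n <- 10000
  y <- rnorm(n)
  d <- 0.8 * y + sqrt(1 - 0.8^2) * rnorm(n)
  r_d <- cor(d, y)
  # identity at r_target = r_d
  expect_identical(make_noisy_descriptor(d, y, r_d), d)
  # closed-form noise sd: sd 1, r 0.8 -> 0.4 gives sqrt(3)
  sd_needed <- sd(d) * sqrt((r_d / 0.4)^2 - 1)
  expect_equal(sd_needed / sd(d), sqrt((r_d / 0.4)^2 - 1))
  for (r_t in c(0.6, 0.4, 0.2)) {
    noisy <- make_noisy_descriptor(d, y, r_t, seed = 101)
    expect_lt(abs(cor(noisy, y) - r_t), 0.02)
  }
  # reproducible under seed
  expect_identical(make_noisy_descriptor(d, y, 0.4, seed = 5),
                   make_noisy_descriptor(d, y, 0.4, seed = 5))
  # monotonicity: more noise, lower |correlation| (on average, here exact
  # for nested noise levels with the same seed)
  r_seq <- vapply(c(0.6, 0.4, 0.2), function(r_t) {
    abs(cor(make_noisy_descriptor(d, y, r_t, seed = 7), y))
  }, numeric(1))
  expect_true(all(diff(r_seq) < 0))
  # infeasible and sign-mismatched targets are rejected
  expect_error(make_noisy_descriptor(d, y, 0.95), "infeasible")
  expect_error(make_noisy_descriptor(d, y, -0.4), "sign")
  expect_error(make_noisy_descriptor(d, y, 0), "non-zero")
})
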