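# Model comparison and latent-space diagnostics: within-fold bootstrap
# significance testing, expected-KL distance from a dataset to the latent
# prior, linear probes of descriptor information, K-means cluster-error
# analysis and PCA projections.

#' Bootstrap comparison of two prediction vectors
#'
#' For each trial, indices are resampled with replacement within each CV
#' fold, the metric is recomputed per fold for both candidates and averaged
#' over folds, and the exceedance direction recorded. The proportion is the
#' larger of the two strict-exceedance frequencies (ties count for neither
#' side); the pair is significantly different when the proportion exceeds
#' `level`.
#'
#' @param pred_a,pred_b Held-out prediction vectors, aligned with `y`.
#' @param y Label vector.
#' @param fold_assignment Integer fold labels from [run_cv()].
#' @param metric `"r2"` (regression) or `"accuracy"` (classification;
#'   predictions are thresholded at 0.5).
#' @param n_trials Number of bootstrap trials.
#' @param level Significance level on the exceedance proportion.
#' @param seed Seed; results are reproducible.
#' @return A `bootstrap_comparison`: `proportion`, `n_trials`,
#'   `significant`, `metric_name`, `direction` (`"a"`, `"b"` or `"none"`),
#'   and the per-direction exceedance counts.
#' @export
bootstrap_compare <- function(pred_a, pred_b, y, fold_assignment,
                              metric = c("r2", "accuracy"),
                              n_trials = 1000L, level = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  n <- length(y)
  stopifnot(length(pred_a) == n, length(pred_b) == n,
            length(fold_assignment) == n)
  folds <- split(seq_len(n), fold_assignment)
  metric_fn <- if (metric == "r2") {
    function(yy, pp) metric_r2(yy, pp)
  } else {
    if (!all(y %in% c(0, 1))) {
      stop("accuracy metric requires binary labels")
    }
    function(yy, pp) mean(yy == as.numeric(pp >= 0.5))
  }
  wins_a <- 0L
  wins_b <- 0L
  with_seed(seed, {
    for (trial in seq_len(n_trials)) {
      score_a <- 0
      score_b <- 0
      n_ok <- 0L
      for (idx in folds) {
        take <- idx[sample.int(length(idx), replace = TRUE)]
        if (metric == "r2" && stats::sd(y[take]) == 0) next
        score_a <- score_a + metric_fn(y[take], pred_a[take])
        score_b <- score_b + metric_fn(y[take], pred_b[take])
        n_ok <- n_ok + 1L
      }
      if (n_ok == 0L) next
      if (score_a > score_b) wins_a <- wins_a + 1L
      if (score_b > score_a) wins_b <- wins_b + 1L
    }
  })
  proportion <- max(wins_a, wins_b) / n_trials
  direction <- if (wins_a > wins_b) "a" else if (wins_b > wins_a) "b"
  else "none"
  structure(list(proportion = proportion, n_trials = n_trials,
                 significant = proportion > level, metric_name = metric,
                 direction = direction, wins_a = wins_a, wins_b = wins_b,
                 level = level),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat("<bootstrap_comparison> metric = ", x$metric_name, ", ", x$n_trials,
      " trials\n  exceedance proportion ", x$proportion, " (a: ", x$wins_a,
      ", b: ", x$wins_b, ") -> ",
      if (x$significant) paste0("significant, '", x$direction, "' higher")
      else "not significant", "\n", sep = "")
  invisible(x)
}

#' Expected-KL distance from a dataset to the latent prior
#'
#' Mean over molecules of the KL divergence between each molecule's encoder
#' posterior and the standard normal prior; the VAE-native measure of how
#' far a set of molecules sits from the modeled chemical space.
#'
#' @param model A trained `smiles_vae`.
#' @param smiles Non-empty character vector of SMILES.
#' @return Non-negative scalar.
#' @export
dataset_prior_distance <- function(model, smiles) {
  if (length(smiles) == 0L) stop("empty SMILES list")
  emb <- embed_molecules(model, smiles, mode = "mean")
  mean(.kl_rows(emb$posterior_means, emb$posterior_logvars))
}

#' Linear probe of information retained in embeddings
#'
#' Cross-validated linear regression of a target on the embedding vectors.
#' The target is standardized (zero mean, unit variance) before fitting so
#' probe errors are comparable across descriptors; held-out RMSE on the raw
#' scale is also returned.
#'
#' @param embeddings A `vae_embedding` or numeric matrix.
#' @param target Numeric vector, one value per embedded molecule.
#' @param n_folds CV folds.
#' @param seed Fold-assignment seed.
#' @return List with `rmse_mean` and `rmse_sd` (standardized scale),
#'   `rmse_raw_mean`, `rmse_raw_sd` and the per-fold values.
#' @export
linear_probe <- function(embeddings, target, n_folds = 10L, seed = 1L) {
  X <- if (inherits(embeddings, "vae_embedding")) embeddings$vectors
  else as.matrix(embeddings)
  stopifnot(nrow(X) == length(target))
  s <- stats::sd(target)
  if (!is.finite(s) || s == 0) stop("constant probe target")
  z <- (target - mean(target)) / s
  cv <- run_cv(model_spec("linear", "regression"), X, z,
               n_folds = n_folds, seed = seed)
  per_fold <- cv$per_fold_metrics$rmse
  list(rmse_mean = mean(per_fold), rmse_sd = stats::sd(per_fold),
       rmse_raw_mean = mean(per_fold) * s,
       rmse_raw_sd = stats::sd(per_fold) * s,
       per_fold_rmse = per_fold)
}

#' K-means cluster-error analysis of the latent space
#'
#' Clusters the embedding vectors with seeded K-means (10 restarts,
#' Euclidean metric on raw coordinates) and reports, per cluster, the mean
#' expected-KL distance to the prior and the RMSE of the held-out
#' predictions over the cluster's members.
#'
#' @param embeddings A `vae_embedding` (posteriors required for the KL
#'   distances).
#' @param held_out_predictions Cross-validated predictions aligned with the
#'   embedded molecules.
#' @param y Observed labels, same alignment.
#' @param k Number of clusters.
#' @param seed K-means seed.
#' @param source_distance Optional scalar distance of the source corpus to
#'   the prior, carried through for reporting.
#' @return A `cluster_diagnostics`: data frame `clusters` (id, size,
#'   mean KL distance, rmse), `assignment`, `source_distance`.
#' @export
cluster_error_analysis <- function(embeddings, held_out_predictions, y,
                                   k = 10L, seed = 1L,
                                   source_distance = NA_real_) {
  stopifnot(inherits(embeddings, "vae_embedding"))
  X <- embeddings$vectors
  n <- nrow(X)
  stopifnot(length(held_out_predictions) == n, length(y) == n)
  if (k > n) stop("k exceeds the number of molecules")
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = 10L))
  kl <- .kl_rows(embeddings$posterior_means, embeddings$posterior_logvars)
  clusters <- do.call(rbind, lapply(seq_len(k), function(cl) {
    members <- km$cluster == cl
    data.frame(cluster = cl, size = sum(members),
               kl_distance = mean(kl[members]),
               rmse = metric_rmse(y[members],
                                  held_out_predictions[members]))
  }))
  structure(list(clusters = clusters, assignment = km$cluster,
                 source_distance = source_distance, k = k),
            class = "cluster_diagnostics")
}

#' @export
print.cluster_diagnostics <- function(x, ...) {
  cat("<cluster_diagnostics> k = ", x$k, sep = "")
  if (is.finite(x$source_distance)) {
    cat(", source-to-prior distance ", signif(x$source_distance, 4),
        sep = "")
  }
  cat("\n")
  print.data.frame(x$clusters, row.names = FALSE, digits = 4)
  invisible(x)
}

#' PCA projection of embeddings
#'
#' Centered (unscaled) principal component scores, as used to visualize
#' latent-space organization.
#'
#' @param embeddings A `vae_embedding` or numeric matrix.
#' @param n_components Number of components (default 2).
#' @return List with `scores` (n x n_components) and
#'   `explained_variance` fractions in decreasing order.
#' @export
pca_project <- function(embeddings, n_components = 2L) {
  X <- if (inherits(embeddings, "vae_embedding")) embeddings$vectors
  else as.matrix(embeddings)
  if (nrow(X) <= n_components) stop("need more rows than components")
  if (all(apply(X, 2, stats::sd) == 0)) {
    stop("degenerate embeddings: all rows identical")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ncomp <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(ncomp), drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(ncomp)])
}
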