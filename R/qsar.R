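# Downstream property models on embeddings or fingerprints: linear
# (least squares / logistic), multilayer perceptron, and a 1-D residual
# network treating the embedding as a length-d single-channel sequence.
# All are trained under seeded k-fold cross-validation.

#' Specify a downstream QSAR model
#'
#' @param family `"linear"`, `"mlp"` or `"resnet1d"`.
#' @param task_type `"regression"` or `"classification"`.
#' @param hidden Hidden-layer widths (mlp).
#' @param blocks,channels,kernel Residual-network shape (resnet1d):
#'   `blocks` pre-activation residual blocks of two convolutions each,
#'   after a stem convolution, before global average pooling and a linear
#'   head.
#' @param epochs,lr,batch_size Training budget for the neural families
#'   (fixed; no nested tuning).
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("linear", "mlp", "resnet1d"),
                       task_type = c("regression", "classification"),
                       hidden = c(64L, 32L), blocks = 4L, channels = 32L,
                       kernel = 5L, epochs = 150L, lr = 1e-2,
                       batch_size = 64L, seed = 1L) {
  family <- match.arg(family)
  task_type <- match.arg(task_type)
  structure(list(family = family, task_type = task_type,
                 hidden = as.integer(hidden), blocks = as.integer(blocks),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_spec")
}

# Metrics -----------------------------------------------------------------

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares about the mean of
#' `y`. Undefined (error) for a constant `y`.
#'
#' @param y Observed values (length >= 2, non-constant).
#' @param pred Predictions, same length.
#' @return Scalar, at most 1.
#' @export
metric_r2 <- function(y, pred) {
  stopifnot(length(y) == length(pred), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant y")
  1 - sum((y - pred)^2) / ss_tot
}

#' Root mean squared error
#'
#' @param y Observed values.
#' @param pred Predictions, same length.
#' @return Non-negative scalar.
#' @export
metric_rmse <- function(y, pred) {
  if (length(y) != length(pred)) stop("length mismatch")
  sqrt(mean((y - pred)^2))
}

#' Accuracy and F1 of binary predictions
#'
#' F1 is computed for the positive class (label 1) and defined as 0 when
#' precision + recall is 0.
#'
#' @param y Observed 0/1 labels.
#' @param pred Predicted 0/1 labels, same length.
#' @return Named vector `c(accuracy, f1)`.
#' @export
metric_accuracy_f1 <- function(y, pred) {
  if (length(y) != length(pred)) stop("length mismatch")
  if (!all(y %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    stop("labels must be binary 0/1")
  }
  tp <- sum(y == 1 & pred == 1)
  fp <- sum(y == 0 & pred == 1)
  fn <- sum(y == 1 & pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(accuracy = mean(y == pred), f1 = f1)
}

# Model fitting ------------------------------------------------------------

# returns a function(newX) -> predictions (probabilities for classification)
.fit_model <- function(spec, X, y) {
  if (spec$family == "linear") {
    if (spec$task_type == "regression") {
      fit <- stats::lm.fit(cbind(1, X), y)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      function(newX) drop(cbind(1, newX) %*% beta)
    } else {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, X), y,
                       family = stats::binomial()))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      function(newX) .sigmoid(drop(cbind(1, newX) %*% beta))
    }
  } else if (spec$family == "mlp") {
    .fit_mlp(spec, X, y)
  } else {
    .fit_resnet1d(spec, X, y)
  }
}

# shared supervised training loop over an arbitrary forward/backward pair
.train_net <- function(spec, X, y, init_fn, fwdbwd_fn) {
  n <- nrow(X)
  classification <- spec$task_type == "classification"
  with_seed(spec$seed, {
    p <- init_fn()
    opt <- adam_init(p)
    for (epoch in seq_len(spec$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = spec$batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + spec$batch_size - 1L, n)]
        res <- fwdbwd_fn(p, X[idx, , drop = FALSE], y[idx], classification)
        st <- adam_step(p, res$grads, opt, lr = spec$lr)
        p <- st$params
        opt <- st$state
      }
    }
    p
  })
}

.mlp_forward <- function(p, X, classification) {
  acts <- list(X)
  n_layers <- length(p)
  for (i in seq_len(n_layers)) {
    a <- dense_forward(acts[[i]], p[[i]])
    if (i < n_layers) a <- .relu(a)
    acts[[i + 1L]] <- a
  }
  out <- drop(acts[[n_layers + 1L]])
  if (classification) out <- .sigmoid(out)
  list(out = out, acts = acts)
}

.fit_mlp <- function(spec, X, y) {
  d <- ncol(X)
  dims <- c(d, spec$hidden, 1L)
  init_fn <- function() {
    lapply(seq_len(length(dims) - 1L), function(i) {
      dense_init(dims[i], dims[i + 1L])
    })
  }
  fwdbwd <- function(p, Xb, yb, classification) {
    fw <- .mlp_forward(p, Xb, classification)
    # d(loss)/d(pre-output): identical form for squared error (scaled) and
    # sigmoid + log loss
    dout <- matrix((fw$out - yb) * (if (classification) 1 else 2) /
                     length(yb), ncol = 1)
    n_layers <- length(p)
    g <- vector("list", n_layers)
    dcur <- dout
    for (i in rev(seq_len(n_layers))) {
      if (i < n_layers) dcur <- dcur * (fw$acts[[i + 1L]] > 0)
      b <- dense_backward(fw$acts[[i]], p[[i]], dcur)
      g[[i]] <- b$grads
      dcur <- b$dX
    }
    list(grads = g)
  }
  p <- .train_net(spec, X, y, init_fn, fwdbwd)
  classification <- spec$task_type == "classification"
  function(newX) .mlp_forward(p, newX, classification)$out
}

# 1-D ResNet: stem conv -> B pre-activation residual blocks -> global
# average pooling -> linear head; the d-dim feature vector is treated as a
# length-d single-channel sequence
.resnet_forward <- function(p, X, classification) {
  n <- nrow(X)
  d <- ncol(X)
  A0 <- array(X, dim = c(n, d, 1L))
  stem <- conv1d_forward(A0, p$stem)
  A <- stem$Y
  cache <- list(A0 = A0, stem = stem, blocks = list())
  for (b in seq_along(p$blocks)) {
    blk <- p$blocks[[b]]
    R1 <- A * (A > 0)
    c1 <- conv1d_forward(R1, blk$conv1)
    R2 <- c1$Y * (c1$Y > 0)
    c2 <- conv1d_forward(R2, blk$conv2)
    cache$blocks[[b]] <- list(A_in = A, R1 = R1, c1 = c1, R2 = R2, c2 = c2)
    A <- A + c2$Y
  }
  Rf <- A * (A > 0)
  pooled <- apply(Rf, c(1L, 3L), mean)
  out <- drop(dense_forward(pooled, p$head))
  if (classification) out <- .sigmoid(out)
  cache$A_final <- A
  cache$Rf <- Rf
  cache$pooled <- pooled
  list(out = out, cache = cache)
}

.fit_resnet1d <- function(spec, X, y) {
  d <- ncol(X)
  C <- spec$channels
  K <- spec$kernel
  init_fn <- function() {
    list(stem = conv1d_init(K, 1L, C),
         blocks = lapply(seq_len(spec$blocks), function(b) {
           list(conv1 = conv1d_init(K, C, C), conv2 = conv1d_init(K, C, C))
         }),
         head = dense_init(C, 1L))
  }
  fwdbwd <- function(p, Xb, yb, classification) {
    fw <- .resnet_forward(p, Xb, classification)
    ca <- fw$cache
    n <- nrow(Xb)
    dout <- matrix((fw$out - yb) * (if (classification) 1 else 2) / n,
                   ncol = 1)
    bh <- dense_backward(ca$pooled, p$head, dout)
    g <- list(head = bh$grads)
    dpooled <- bh$dX
    dRf <- array(rep(dpooled, each = 1), dim = dim(ca$Rf))
    for (ch in seq_len(dim(ca$Rf)[3])) {
      dRf[, , ch] <- matrix(dpooled[, ch] / d, n, d)
    }
    dA <- dRf * (ca$A_final > 0)
    g$blocks <- vector("list", length(p$blocks))
    for (b in rev(seq_along(p$blocks))) {
      blk <- p$blocks[[b]]
      cb <- ca$blocks[[b]]
      b2 <- conv1d_backward(cb$R2, blk$conv2, cb$c2, dA)
      dR2 <- b2$dX * (cb$c1$Y > 0)
      b1 <- conv1d_backward(cb$R1, blk$conv1, cb$c1, dR2)
      g$blocks[[b]] <- list(conv1 = b1$grads, conv2 = b2$grads)
      dA <- dA + b1$dX * (cb$A_in > 0)
    }
    bs <- conv1d_backward(ca$A0, p$stem, ca$stem, dA)
    g$stem <- bs$grads
    list(grads = g)
  }
  p <- .train_net(spec, X, y, init_fn, fwdbwd)
  classification <- spec$task_type == "classification"
  function(newX) .resnet_forward(p, newX, classification)$out
}

# Cross-validation ----------------------------------------------------------

# seeded fold assignment: shuffled contiguous split, stratified by class
# for classification
.make_folds <- function(y, n_folds, seed, task_type) {
  n <- length(y)
  with_seed(seed, {
    assign_contiguous <- function(idx) {
      sizes <- rep(length(idx) %/% n_folds, n_folds)
      extra <- length(idx) %% n_folds
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      rep(seq_len(n_folds), sizes)
    }
    fold <- integer(n)
    if (task_type == "classification") {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- assign_contiguous(idx)
      }
    } else {
      idx <- sample.int(n)
      fold[idx] <- assign_contiguous(idx)
    }
    fold
  })
}

#' K-fold cross-validation of a QSAR model
#'
#' Folds are a seed-deterministic partition with sizes differing by at most
#' one (stratified by class for classification). Each fold's model is
#' trained only on the remaining folds; every molecule's prediction comes
#' from the model that held it out.
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature matrix (embeddings or fingerprints).
#' @param y Label vector.
#' @param n_folds Number of folds (default 10).
#' @param seed Seed controlling the partition (and, combined with the spec
#'   seed, neural-model training).
#' @return A `cv_result`: `fold_assignment`, `predictions` (held-out, in
#'   input order; probabilities and `class_predictions` for
#'   classification), `per_fold_metrics` data frame, `aggregate`
#'   (mean and sd per metric).
#' @export
run_cv <- function(spec, X, y, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X contains non-finite values")
  n <- nrow(X)
  if (n < n_folds) stop("need at least n_folds = ", n_folds, " samples")
  if (length(y) != n) stop("y length does not match X")
  fold <- .make_folds(y, n_folds, seed, spec$task_type)
  preds <- numeric(n)
  metrics <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    sp <- spec
    sp$seed <- spec$seed + f
    predict_fn <- .fit_model(sp, X[!test, , drop = FALSE], y[!test])
    p_f <- predict_fn(X[test, , drop = FALSE])
    preds[test] <- p_f
    metrics[[f]] <- if (spec$task_type == "regression") {
      c(r2 = metric_r2(y[test], p_f), rmse = metric_rmse(y[test], p_f))
    } else {
      metric_accuracy_f1(y[test], as.numeric(p_f >= 0.5))
    }
  }
  per_fold <- as.data.frame(do.call(rbind, metrics))
  per_fold$fold <- seq_len(n_folds)
  agg <- data.frame(
    metric = setdiff(names(per_fold), "fold"),
    mean = vapply(per_fold[setdiff(names(per_fold), "fold")], mean,
                  numeric(1)),
    sd = vapply(per_fold[setdiff(names(per_fold), "fold")], stats::sd,
                numeric(1)))
  rownames(agg) <- NULL
  structure(list(spec = spec, fold_assignment = fold, predictions = preds,
                 class_predictions = if (spec$task_type == "classification")
                   as.numeric(preds >= 0.5) else NULL,
                 y = y, per_fold_metrics = per_fold, aggregate = agg,
                 n_folds = n_folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$spec$family, " (", x$spec$task_type, "), ",
      x$n_folds, "-fold CV on ", length(x$y), " molecules\n", sep = "")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}

#' Write a CV result to JSON
#'
#' @param result A `cv_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(result, path) {
  stopifnot(inherits(result, "cv_result"))
  jsonlite::write_json(list(
    family = result$spec$family, task_type = result$spec$task_type,
    n_folds = result$n_folds, seed = result$seed,
    fold_assignment = result$fold_assignment,
    predictions = result$predictions,
    per_fold_metrics = result$per_fold_metrics,
    aggregate = result$aggregate), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Fingerprint baseline --------------------------------------------------------

#' Circular fingerprint baseline features
#'
#' Morgan-type circular fingerprints of radius 2 (ECFP4), folded to
#' `n_bits` by OR-ing hashed positions. Deterministic per structure.
#'
#' @param dataset A `mol_dataset` (canonicalized upstream).
#' @param n_bits Folded fingerprint length.
#' @return Binary matrix, `nrow(dataset)` x `n_bits`.
#' @export
build_baseline_fingerprint <- function(dataset, n_bits = 1024L) {
  stopifnot(inherits(dataset, "mol_dataset"), nrow(dataset) > 0)
  mols <- ChemmineOB::forEachMol(
    "SMILES", paste(dataset$canonical_smiles, collapse = "\n"), identity)
  raw <- ChemmineOB::fingerprint_OB(mols, "ECFP4")
  raw <- matrix(raw, nrow = nrow(dataset))
  width <- ncol(raw)
  if (width <= n_bits) return(raw[, seq_len(min(width, n_bits)), drop = FALSE])
  folded <- matrix(0, nrow(raw), n_bits)
  for (s in seq_len(width %/% n_bits)) {
    cols <- ((s - 1L) * n_bits + 1L):(s * n_bits)
    folded <- pmax(folded, raw[, cols, drop = FALSE])
  }
  folded
}
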