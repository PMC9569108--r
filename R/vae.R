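# SMILES variational autoencoders. Two variants:
#   cvae - convolutional encoder, GRU decoder, 3-hidden-layer MLP predictor
#   pvae - GRU encoder and decoder, character-frequency-weighted
#          reconstruction loss, single linear predictor
# Both map a SMILES string to a Gaussian posterior over the latent space and
# are trained on reconstruction + KL, optionally jointly with a descriptor
# predictor head on the latent code.

.PAD <- "<pad>"
.BOS <- "<s>"
.EOS <- "</s>"

# Vocabulary ---------------------------------------------------------------

#' Build a SMILES token vocabulary
#'
#' Tokens are the sorted unique SMILES symbols of the corpus plus pad, start
#' and end markers. Deterministic for a fixed corpus.
#'
#' @param corpus Character vector of SMILES strings.
#' @param max_length Sequence length after adding start/end and padding;
#'   defaults to the longest corpus SMILES plus two. Every corpus SMILES
#'   must fit in `max_length - 2` tokens.
#' @return A `vae_vocab`: list with `tokens`, `token_to_index`, `max_length`
#'   and the special-token indices.
#' @export
build_vocabulary <- function(corpus, max_length = NULL) {
  stopifnot(is.character(corpus), length(corpus) > 0)
  toks <- smiles_tokens(corpus)
  lens <- lengths(toks)
  if (is.null(max_length)) max_length <- max(lens) + 2L
  too_long <- lens > max_length - 2L
  if (any(too_long)) {
    stop("SMILES too long for max_length = ", max_length, ": ",
         paste(utils::head(corpus[too_long], 5), collapse = ", "))
  }
  symbols <- sort(unique(unlist(toks)))
  tokens <- c(.PAD, .BOS, .EOS, symbols)
  structure(list(tokens = tokens,
                 token_to_index = stats::setNames(seq_along(tokens), tokens),
                 max_length = as.integer(max_length),
                 pad = 1L, bos = 2L, eos = 3L),
            class = "vae_vocab")
}

#' @export
print.vae_vocab <- function(x, ...) {
  cat("<vae_vocab> ", length(x$tokens), " tokens, max_length ",
      x$max_length, "\n  ", paste(x$tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Encode SMILES as padded index sequences
#'
#' Each string becomes `start, symbols..., end` right-padded to
#' `max_length`; [detokenize()] inverts the encoding.
#'
#' @param smiles Character vector.
#' @param vocab A `vae_vocab`.
#' @return Integer matrix, `length(smiles)` x `max_length`.
#' @export
tokenize <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "vae_vocab"))
  toks <- smiles_tokens(smiles)
  n <- length(smiles)
  out <- matrix(vocab$pad, n, vocab$max_length)
  for (i in seq_len(n)) {
    idx <- vocab$token_to_index[toks[[i]]]
    if (anyNA(idx)) {
      stop("unknown token(s) in '", smiles[[i]], "': ",
           paste(unique(toks[[i]][is.na(idx)]), collapse = " "))
    }
    if (length(idx) > vocab$max_length - 2L) {
      stop("SMILES exceeds max_length: ", smiles[[i]])
    }
    out[i, seq_len(length(idx) + 2L)] <- c(vocab$bos, idx, vocab$eos)
  }
  out
}

#' Decode index sequences back to SMILES
#'
#' @param ids Integer matrix from [tokenize()] (or a single integer vector).
#' @param vocab The `vae_vocab` used to encode.
#' @return Character vector of SMILES.
#' @export
detokenize <- function(ids, vocab) {
  if (is.vector(ids)) ids <- matrix(ids, nrow = 1)
  apply(ids, 1L, function(row) {
    row <- row[row != vocab$pad & row != vocab$bos]
    stop_at <- match(vocab$eos, row)
    if (!is.na(stop_at)) row <- row[seq_len(stop_at - 1L)]
    paste(vocab$tokens[row], collapse = "")
  })
}

#' Character-prevalence decoder weights
#'
#' The penalized reconstruction loss weights each output token by the
#' inverse relative frequency of the corresponding character in the corpus:
#' `w_c = (N / (V * n_c))^exponent`, with `n_c` the corpus count of token
#' `c`, `N` the total token count and `V` the number of distinct observed
#' tokens. A uniform corpus therefore yields all-ones weights. Tokens never
#' observed in the corpus (including the end marker) receive the maximum
#' computed weight; the pad weight is set explicitly (pad positions are
#' masked out of the loss anyway).
#'
#' @param corpus Character vector of SMILES.
#' @param vocab A `vae_vocab`.
#' @param pad_weight Weight assigned to the pad token.
#' @param exponent Softening exponent applied to the raw weights.
#' @return Named numeric vector over `vocab$tokens`.
#' @export
char_weights <- function(corpus, vocab, pad_weight = 1, exponent = 1) {
  stopifnot(length(corpus) > 0, inherits(vocab, "vae_vocab"))
  all_toks <- unlist(smiles_tokens(corpus))
  counts <- table(all_toks)
  n_total <- sum(counts)
  v_seen <- length(counts)
  w <- rep(NA_real_, length(vocab$tokens))
  names(w) <- vocab$tokens
  seen <- intersect(names(counts), vocab$tokens)
  w[seen] <- (n_total / (v_seen * as.numeric(counts[seen])))^exponent
  w_max <- max(w, na.rm = TRUE)
  w[is.na(w)] <- w_max
  w[vocab$tokens[vocab$pad]] <- pad_weight
  w
}

# KL divergence ------------------------------------------------------------

#' KL divergence of a diagonal Gaussian posterior from the standard prior
#'
#' Closed form `0.5 * sum(mu^2 + exp(logvar) - logvar - 1)`; zero exactly
#' when the posterior equals the prior (`mu = 0`, `logvar = 0`).
#'
#' @param mu Numeric vector of posterior means.
#' @param logvar Numeric vector of posterior log-variances (same length).
#' @return Non-negative scalar.
#' @export
kl_to_prior <- function(mu, logvar) {
  if (length(mu) != length(logvar)) stop("mu and logvar lengths differ")
  if (any(!is.finite(mu)) || any(!is.finite(logvar))) {
    stop("non-finite posterior parameters")
  }
  0.5 * sum(mu^2 + exp(logvar) - logvar - 1)
}

# row-wise KL for n x L matrices
.kl_rows <- function(mu, logvar) {
  0.5 * rowSums(mu^2 + exp(logvar) - logvar - 1)
}

# Loss ----------------------------------------------------------------------

.softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  E <- exp(X - m)
  E / rowSums(E)
}

#' VAE training loss
#'
#' `total = reconstruction + beta * kl + lambda_pred * predictor`.
#' Reconstruction is token-wise cross-entropy over non-pad target positions,
#' optionally weighted per target token, averaged over the non-pad
#' positions of the batch; `kl` is the batch mean of [kl_to_prior()];
#' `predictor` is mean squared error on (standardized) descriptor targets.
#'
#' @param decoder_logits `n x T x V` array of unnormalized decoder scores.
#' @param target_tokens `n x T` integer matrix of target indices.
#' @param mu,logvar `n x L` posterior parameter matrices.
#' @param weights Optional length-`V` token weight vector.
#' @param beta KL weight.
#' @param pred_out,pred_targets Optional `n x K` predictor output and target
#'   matrices (both or neither).
#' @param lambda_pred Predictor-loss weight.
#' @param pad_index Index of the pad token in the vocabulary.
#' @return List with `total` and `components` (reconstruction, kl,
#'   predictor).
#' @export
vae_loss <- function(decoder_logits, target_tokens, mu, logvar,
                     weights = NULL, beta = 1, pred_out = NULL,
                     pred_targets = NULL, lambda_pred = 1, pad_index = 1L) {
  stopifnot(is.array(decoder_logits), length(dim(decoder_logits)) == 3L)
  n <- dim(decoder_logits)[1]
  T_len <- dim(decoder_logits)[2]
  V <- dim(decoder_logits)[3]
  if (!all(dim(target_tokens) == c(n, T_len))) {
    stop("target_tokens shape does not match decoder_logits")
  }
  if (xor(is.null(pred_out), is.null(pred_targets))) {
    stop("pred_out and pred_targets must be given together")
  }
  recon <- 0
  n_pos <- 0L
  for (t in seq_len(T_len)) {
    tgt <- target_tokens[, t]
    live <- tgt != pad_index
    if (!any(live)) next
    P <- .softmax_rows(matrix(decoder_logits[, t, ], nrow = n))
    logp <- log(pmax(P[cbind(which(live), tgt[live])], 1e-12))
    w <- if (is.null(weights)) 1 else weights[tgt[live]]
    recon <- recon - sum(w * logp)
    n_pos <- n_pos + sum(live)
  }
  recon <- if (n_pos > 0) recon / n_pos else 0
  kl <- mean(.kl_rows(mu, logvar))
  pred <- if (is.null(pred_out)) 0 else mean((pred_out - pred_targets)^2)
  list(total = recon + beta * kl + lambda_pred * pred,
       components = c(reconstruction = recon, kl = kl, predictor = pred))
}

# Configuration --------------------------------------------------------------

#' VAE architecture and training configuration
#'
#' @param variant `"pvae"` (GRU encoder/decoder, weighted reconstruction,
#'   linear predictor) or `"cvae"` (convolutional encoder, GRU decoder,
#'   3-hidden-layer MLP predictor).
#' @param latent_dim Latent dimensionality (196 in the full-scale setting;
#'   smaller values are practical for small corpora).
#' @param hidden_dim GRU hidden width.
#' @param conv_channels,conv_kernels Convolutional encoder stack (cvae).
#' @param predictor_hidden Hidden widths of the cvae predictor MLP; must
#'   have exactly three entries.
#' @param beta KL weight.
#' @param lambda_pred Predictor-loss weight (0 disables joint training).
#' @param use_char_weights Weight the reconstruction loss by character
#'   prevalence (the pvae penalty); defaults to `variant == "pvae"`.
#' @param char_weight_exponent Softening exponent for the penalty weights.
#' @param kl_warmup Epochs of linear KL annealing from 0 to `beta`.
#' @param epochs,batch_size,lr,seed Training-loop controls.
#' @return A validated `vae_config` list.
#' @export
vae_config <- function(variant = c("pvae", "cvae"), latent_dim = 196L,
                       hidden_dim = 64L, conv_channels = c(32L, 32L),
                       conv_kernels = c(5L, 5L),
                       predictor_hidden = c(64L, 64L, 64L),
                       beta = 1, lambda_pred = 1,
                       use_char_weights = NULL, char_weight_exponent = 1,
                       kl_warmup = 0L, epochs = 100L, batch_size = 32L,
                       lr = 1e-3, seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(use_char_weights)) use_char_weights <- variant == "pvae"
  stopifnot(latent_dim >= 1, hidden_dim >= 1, beta >= 0, lambda_pred >= 0,
            epochs >= 1, batch_size >= 1, lr > 0)
  if (variant == "cvae") {
    if (length(predictor_hidden) != 3L) {
      stop("the cvae predictor must have exactly 3 hidden layers")
    }
    if (length(conv_channels) != length(conv_kernels)) {
      stop("conv_channels and conv_kernels lengths differ")
    }
  }
  structure(list(variant = variant, latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 conv_channels = as.integer(conv_channels),
                 conv_kernels = as.integer(conv_kernels),
                 predictor_hidden = as.integer(predictor_hidden),
                 beta = beta, lambda_pred = lambda_pred,
                 use_char_weights = use_char_weights,
                 char_weight_exponent = char_weight_exponent,
                 kl_warmup = as.integer(kl_warmup),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, seed = as.integer(seed)),
            class = "vae_config")
}

# Parameter initialization ---------------------------------------------------

.vae_init_params <- function(config, vocab, n_desc) {
  V <- length(vocab$tokens)
  L <- config$latent_dim
  H <- config$hidden_dim
  p <- list()
  if (config$variant == "pvae") {
    p$enc_gru <- gru_init(V, H)
    enc_out <- H
  } else {
    chans <- c(V, config$conv_channels)
    p$enc_conv <- lapply(seq_along(config$conv_channels), function(i) {
      conv1d_init(config$conv_kernels[i], chans[i], chans[i + 1L])
    })
    flat <- vocab$max_length * utils::tail(config$conv_channels, 1)
    p$enc_dense <- dense_init(flat, H)
    enc_out <- H
  }
  p$W_mu <- dense_init(enc_out, L)
  p$W_lv <- dense_init(enc_out, L)
  p$dec_init <- dense_init(L, H)
  p$dec_gru <- gru_init(V + L, H)
  p$dec_out <- dense_init(H, V)
  if (n_desc > 0L) {
    if (config$variant == "pvae") {
      p$pred <- list(dense_init(L, n_desc))
    } else {
      dims <- c(L, config$predictor_hidden, n_desc)
      p$pred <- lapply(seq_len(length(dims) - 1L), function(i) {
        dense_init(dims[i], dims[i + 1L])
      })
    }
  }
  p
}

# Forward/backward ------------------------------------------------------------

.one_hot <- function(idx, V) {
  n <- length(idx)
  M <- matrix(0, n, V)
  M[cbind(seq_len(n), idx)] <- 1
  M
}

# encoder forward: returns mu, logvar and caches needed for backprop
.encode_forward <- function(p, config, ids, vocab) {
  n <- nrow(ids)
  V <- length(vocab$tokens)
  if (config$variant == "pvae") {
    end_pos <- apply(ids, 1L, function(r) match(vocab$eos, r))
    end_pos[is.na(end_pos)] <- ncol(ids)
    T_enc <- max(end_pos)
    X_list <- lapply(seq_len(T_enc), function(t) .one_hot(ids[, t], V))
    fwd <- gru_forward(X_list, p$enc_gru, matrix(0, n, config$hidden_dim))
    h_final <- matrix(0, n, config$hidden_dim)
    for (t in unique(end_pos)) {
      rows <- which(end_pos == t)
      h_final[rows, ] <- fwd$H_list[[t]][rows, , drop = FALSE]
    }
    cache <- list(X_list = X_list, fwd = fwd, end_pos = end_pos,
                  T_enc = T_enc)
  } else {
    T_len <- vocab$max_length
    X <- array(0, dim = c(n, T_len, V))
    for (t in seq_len(T_len)) X[, t, ] <- .one_hot(ids[, t], V)
    conv_in <- list(X)
    conv_fwd <- list()
    A <- X
    for (i in seq_along(p$enc_conv)) {
      cf <- conv1d_forward(A, p$enc_conv[[i]])
      conv_fwd[[i]] <- cf
      A <- .relu(cf$Y)
      conv_in[[i + 1L]] <- A
    }
    flat <- matrix(A, n, T_len * dim(A)[3])
    dpre <- dense_forward(flat, p$enc_dense)
    h_final <- .relu(dpre)
    cache <- list(conv_in = conv_in, conv_fwd = conv_fwd, flat = flat,
                  dpre = dpre, T_len = T_len)
  }
  mu <- dense_forward(h_final, p$W_mu)
  lv <- dense_forward(h_final, p$W_lv)
  cache$h_final <- h_final
  list(mu = mu, logvar = lv, cache = cache)
}

# encoder backward from dmu, dlv; returns parameter grads
.encode_backward <- function(p, config, cache, dmu, dlv, vocab) {
  g <- list()
  bm <- dense_backward(cache$h_final, p$W_mu, dmu)
  bl <- dense_backward(cache$h_final, p$W_lv, dlv)
  g$W_mu <- bm$grads
  g$W_lv <- bl$grads
  dh <- bm$dX + bl$dX
  if (config$variant == "pvae") {
    dH_list <- vector("list", cache$T_enc)
    for (t in unique(cache$end_pos)) {
      rows <- cache$end_pos == t
      M <- dh * 0
      M[rows, ] <- dh[rows, , drop = FALSE]
      dH_list[[t]] <- M
    }
    bg <- gru_backward(cache$X_list, p$enc_gru, cache$fwd, dH_list)
    g$enc_gru <- bg$grads
  } else {
    dpre_grad <- dh * (cache$dpre > 0)
    bd <- dense_backward(cache$flat, p$enc_dense, dpre_grad)
    g$enc_dense <- bd$grads
    n <- nrow(dh)
    c_last <- utils::tail(config$conv_channels, 1)
    dA <- array(bd$dX, dim = c(n, cache$T_len, c_last))
    g$enc_conv <- vector("list", length(p$enc_conv))
    for (i in rev(seq_along(p$enc_conv))) {
      dA <- dA * (conv_relu_mask <- (cache$conv_fwd[[i]]$Y > 0))
      bc <- conv1d_backward(cache$conv_in[[i]], p$enc_conv[[i]],
                            cache$conv_fwd[[i]], dA)
      g$enc_conv[[i]] <- bc$grads
      dA <- bc$dX
    }
  }
  g
}

# predictor head forward/backward (relu MLP for cvae, linear for pvae)
.pred_forward <- function(p_pred, z) {
  acts <- list(z)
  n_layers <- length(p_pred)
  for (i in seq_len(n_layers)) {
    a <- dense_forward(acts[[i]], p_pred[[i]])
    if (i < n_layers) a <- .relu(a)
    acts[[i + 1L]] <- a
  }
  list(out = acts[[n_layers + 1L]], acts = acts)
}

.pred_backward <- function(p_pred, cache, dout) {
  n_layers <- length(p_pred)
  g <- vector("list", n_layers)
  d <- dout
  for (i in rev(seq_len(n_layers))) {
    if (i < n_layers) d <- d * (cache$acts[[i + 1L]] > 0)
    b <- dense_backward(cache$acts[[i]], p_pred[[i]], d)
    g[[i]] <- b$grads
    d <- b$dX
  }
  list(grads = g, dz = d)
}

# full forward + backward for one batch; returns loss components and grads
.vae_batch_grad <- function(p, config, ids, vocab, eps, weights,
                            pred_targets, beta_eff) {
  n <- nrow(ids)
  V <- length(vocab$tokens)
  L <- config$latent_dim
  enc <- .encode_forward(p, config, ids, vocab)
  mu <- enc$mu
  lv <- enc$logvar
  z <- mu + exp(lv / 2) * eps
  # decoder teacher forcing: input t is token t (start first), target t+1
  tgt_cols <- 2:ncol(ids)
  live_any <- vapply(tgt_cols, function(t) any(ids[, t] != vocab$pad),
                     logical(1))
  T_dec <- max(which(live_any))
  h0pre <- dense_forward(z, p$dec_init)
  h0 <- tanh(h0pre)
  X_dec <- lapply(seq_len(T_dec), function(t) {
    cbind(.one_hot(ids[, t], V), z)
  })
  dec <- gru_forward(X_dec, p$dec_gru, h0)
  n_pos <- 0L
  recon <- 0
  dH_list <- vector("list", T_dec)
  dlogit_list <- vector("list", T_dec)
  for (t in seq_len(T_dec)) {
    tgt <- ids[, t + 1L]
    live <- tgt != vocab$pad
    P <- .softmax_rows(dense_forward(dec$H_list[[t]], p$dec_out))
    D <- P
    D[cbind(seq_len(n), tgt)] <- D[cbind(seq_len(n), tgt)] - 1
    w_row <- if (is.null(weights)) rep(1, n) else weights[tgt]
    w_row[!live] <- 0
    logp <- log(pmax(P[cbind(seq_len(n), tgt)], 1e-12))
    recon <- recon - sum(w_row * logp)
    n_pos <- n_pos + sum(live)
    dlogit_list[[t]] <- D * w_row
  }
  recon <- recon / n_pos
  g <- list()
  g_out_W <- p$dec_out$W * 0
  g_out_b <- p$dec_out$b * 0
  for (t in seq_len(T_dec)) {
    dlog <- dlogit_list[[t]] / n_pos
    b <- dense_backward(dec$H_list[[t]], p$dec_out, dlog)
    g_out_W <- g_out_W + b$grads$W
    g_out_b <- g_out_b + b$grads$b
    dH_list[[t]] <- b$dX
  }
  g$dec_out <- list(W = g_out_W, b = g_out_b)
  bg <- gru_backward(X_dec, p$dec_gru, dec, dH_list)
  g$dec_gru <- bg$grads
  dz <- matrix(0, n, L)
  for (t in seq_len(T_dec)) {
    dz <- dz + bg$dX_list[[t]][, (V + 1L):(V + L), drop = FALSE]
  }
  dh0 <- if (is.null(bg$dh0)) h0 * 0 else bg$dh0
  dh0pre <- dh0 * (1 - h0^2)
  bi <- dense_backward(z, p$dec_init, dh0pre)
  g$dec_init <- bi$grads
  dz <- dz + bi$dX
  # predictor
  pred_loss <- 0
  if (!is.null(pred_targets) && !is.null(p$pred) && config$lambda_pred > 0) {
    pf <- .pred_forward(p$pred, z)
    err <- pf$out - pred_targets
    pred_loss <- mean(err^2)
    dout <- config$lambda_pred * 2 * err / length(err)
    pb <- .pred_backward(p$pred, pf, dout)
    g$pred <- pb$grads
    dz <- dz + pb$dz
  } else if (!is.null(p$pred)) {
    g$pred <- lapply(p$pred, function(q) list(W = q$W * 0, b = q$b * 0))
  }
  kl <- mean(.kl_rows(mu, lv))
  dmu <- dz + beta_eff * mu / n
  dlv <- dz * eps * 0.5 * exp(lv / 2) + beta_eff * 0.5 * (exp(lv) - 1) / n
  ge <- .encode_backward(p, config, enc$cache, dmu, dlv, vocab)
  g <- c(g, ge)
  list(grads = g,
       components = c(reconstruction = recon, kl = kl,
                      predictor = pred_loss),
       total = recon + beta_eff * kl + config$lambda_pred * pred_loss)
}

# Training --------------------------------------------------------------------

#' Train a SMILES VAE, optionally jointly with a descriptor predictor
#'
#' Optimizes reconstruction + KL (+ descriptor MSE when a descriptor table
#' is supplied) with Adam. Descriptor targets are standardized to zero mean
#' and unit variance using corpus statistics, which are stored in the model
#' so probes and downstream use stay consistent. One integer seed controls
#' weight initialization, batch shuffling and reparameterization noise.
#'
#' @param config A [vae_config()].
#' @param corpus Character vector of training SMILES.
#' @param descriptor_table Optional `desc_table` (or data frame) covering
#'   every corpus molecule, one row per molecule in corpus order.
#' @param vocab Optional pre-built vocabulary (built from the corpus when
#'   omitted).
#' @return A `smiles_vae` object: configuration, vocabulary, learned
#'   parameters, descriptor standardization and the per-epoch loss history.
#' @export
train_vae <- function(config, corpus, descriptor_table = NULL,
                      vocab = NULL) {
  stopifnot(inherits(config, "vae_config"), length(corpus) >= 1)
  if (is.null(vocab)) vocab <- build_vocabulary(corpus)
  ids <- tokenize(corpus, vocab)
  n <- length(corpus)
  desc_names <- character(0)
  desc_stats <- NULL
  targets <- NULL
  if (!is.null(descriptor_table)) {
    dt <- as.data.frame(descriptor_table)
    if (nrow(dt) != n) {
      stop("descriptor_table must cover every corpus molecule (",
           nrow(dt), " rows for ", n, " molecules)")
    }
    desc_names <- names(dt)
    desc_stats <- data.frame(
      descriptor = desc_names,
      mean = vapply(dt, mean, numeric(1)),
      sd = vapply(dt, stats::sd, numeric(1)))
    if (any(desc_stats$sd == 0)) {
      stop("constant descriptor target(s): ",
           paste(desc_stats$descriptor[desc_stats$sd == 0], collapse = ", "))
    }
    targets <- sweep(sweep(as.matrix(dt), 2, desc_stats$mean), 2,
                     desc_stats$sd, "/")
  }
  weights <- NULL
  if (config$use_char_weights) {
    weights <- char_weights(corpus, vocab,
                            exponent = config$char_weight_exponent)
  }
  model <- with_seed(config$seed, {
    p <- .vae_init_params(config, vocab, length(desc_names))
    opt <- adam_init(p)
    history <- data.frame(epoch = integer(0), reconstruction = numeric(0),
                          kl = numeric(0), predictor = numeric(0),
                          total = numeric(0))
    L <- config$latent_dim
    for (epoch in seq_len(config$epochs)) {
      beta_eff <- if (config$kl_warmup > 0) {
        config$beta * min(1, epoch / config$kl_warmup)
      } else {
        config$beta
      }
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      comp_sum <- c(reconstruction = 0, kl = 0, predictor = 0)
      tot_sum <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        eps <- matrix(stats::rnorm(length(idx) * L), length(idx), L)
        res <- .vae_batch_grad(p, config, ids[idx, , drop = FALSE], vocab,
                               eps, weights,
                               if (is.null(targets)) NULL
                               else targets[idx, , drop = FALSE],
                               beta_eff)
        if (!is.finite(res$total)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        st <- adam_step(p, res$grads, opt, lr = config$lr)
        p <- st$params
        opt <- st$state
        comp_sum <- comp_sum + res$components * length(idx)
        tot_sum <- tot_sum + res$total * length(idx)
      }
      history <- rbind(history, data.frame(
        epoch = epoch,
        reconstruction = comp_sum[["reconstruction"]] / n,
        kl = comp_sum[["kl"]] / n,
        predictor = comp_sum[["predictor"]] / n,
        total = tot_sum / n))
    }
    list(params = p, history = history)
  })
  structure(list(config = config, vocab = vocab, params = model$params,
                 descriptor_names = desc_names,
                 descriptor_stats = desc_stats,
                 char_weights = weights,
                 history = model$history),
            class = "smiles_vae")
}

#' @export
print.smiles_vae <- function(x, ...) {
  cat("<smiles_vae> ", toupper(x$config$variant), ", latent ",
      x$config$latent_dim, ", hidden ", x$config$hidden_dim, ", vocab ",
      length(x$vocab$tokens), " tokens\n", sep = "")
  if (length(x$descriptor_names)) {
    cat("  jointly trained predictor head: ",
        paste(x$descriptor_names, collapse = ", "), "\n", sep = "")
  }
  h <- utils::tail(x$history, 1)
  cat("  after ", nrow(x$history), " epochs: reconstruction ",
      signif(h$reconstruction, 4), ", kl ", signif(h$kl, 4),
      if (length(x$descriptor_names)) paste0(", predictor ",
                                             signif(h$predictor, 4)),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.smiles_vae <- function(object, ...) {
  print(object)
  cat("loss history (every ", max(1L, nrow(object$history) %/% 10L),
      " epochs):\n", sep = "")
  idx <- unique(c(seq(1L, nrow(object$history),
                      by = max(1L, nrow(object$history) %/% 10L)),
                  nrow(object$history)))
  print(object$history[idx, ], row.names = FALSE)
  invisible(object)
}

#' @export
plot.smiles_vae <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$reconstruction, h$kl, h$predictor),
                    type = "l", lty = 1, col = c("black", "red", "blue"),
                    xlab = "epoch", ylab = "loss component", ...)
  graphics::legend("topright", c("reconstruction", "kl", "predictor"),
                   col = c("black", "red", "blue"), lty = 1, bty = "n")
  invisible(x)
}

# Embedding --------------------------------------------------------------------

#' Encode molecules into the latent space
#'
#' @param model A trained `smiles_vae`.
#' @param smiles Character vector of SMILES (must tokenize under the model
#'   vocabulary).
#' @param mode `"mean"` returns the posterior means (deterministic);
#'   `"sample"` draws one reparameterized sample per molecule.
#' @param seed Seed for `"sample"` mode.
#' @return A `vae_embedding`: list with `vectors` (n x latent matrix),
#'   `posterior_means`, `posterior_logvars`, `mode`, `seed`.
#' @export
embed_molecules <- function(model, smiles, mode = c("mean", "sample"),
                            seed = 1L) {
  stopifnot(inherits(model, "smiles_vae"))
  mode <- match.arg(mode)
  ids <- tokenize(smiles, model$vocab)
  enc <- .encode_forward(model$params, model$config, ids, model$vocab)
  vectors <- if (mode == "mean") {
    enc$mu
  } else {
    with_seed(seed, enc$mu + exp(enc$logvar / 2) *
                matrix(stats::rnorm(length(enc$mu)), nrow(enc$mu)))
  }
  structure(list(vectors = vectors, posterior_means = enc$mu,
                 posterior_logvars = enc$logvar, mode = mode,
                 seed = if (mode == "sample") seed else NA_integer_),
            class = "vae_embedding")
}

#' @export
print.vae_embedding <- function(x, ...) {
  cat("<vae_embedding> ", nrow(x$vectors), " molecules x ",
      ncol(x$vectors), " latent dims (mode = ", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Predict from a trained VAE
#'
#' `type = "embedding"` returns posterior-mean latent vectors;
#' `type = "descriptors"` runs the jointly trained predictor head and
#' returns descriptor predictions on the original (de-standardized) scale.
#'
#' @param object A `smiles_vae`.
#' @param smiles Character vector of SMILES.
#' @param type What to predict.
#' @param ... Unused.
#' @return A numeric matrix.
#' @export
predict.smiles_vae <- function(object, smiles,
                               type = c("embedding", "descriptors"), ...) {
  type <- match.arg(type)
  emb <- embed_molecules(object, smiles, mode = "mean")
  if (type == "embedding") return(emb$vectors)
  if (!length(object$descriptor_names)) {
    stop("model was trained without a predictor head")
  }
  out <- .pred_forward(object$params$pred, emb$vectors)$out
  out <- sweep(sweep(out, 2, object$descriptor_stats$sd, "*"), 2,
               object$descriptor_stats$mean, "+")
  colnames(out) <- object$descriptor_names
  out
}

# Reconstruction ----------------------------------------------------------------

# batched greedy decoding from given latent codes
.greedy_decode <- function(model, z) {
  p <- model$params
  vocab <- model$vocab
  V <- length(vocab$tokens)
  n <- nrow(z)
  h <- tanh(dense_forward(z, p$dec_init))
  prev <- rep(vocab$bos, n)
  done <- rep(FALSE, n)
  out <- matrix(vocab$pad, n, vocab$max_length)
  for (t in seq_len(vocab$max_length - 1L)) {
    X <- cbind(.one_hot(prev, V), z)
    step <- gru_forward(list(X), p$dec_gru, h)
    h <- step$H_list[[1L]]
    logits <- dense_forward(h, p$dec_out)
    nxt <- max.col(logits, ties.method = "first")
    nxt[done] <- vocab$pad
    out[, t] <- nxt
    done <- done | nxt == vocab$eos
    prev <- nxt
    if (all(done)) break
  }
  out
}

#' Exact-reconstruction accuracy
#'
#' Fraction of molecules whose greedy decoding from the posterior mean
#' reproduces the input SMILES string exactly. Per-character accuracy over
#' the aligned prefix is returned as an attribute.
#'
#' @param model A trained `smiles_vae`.
#' @param smiles Non-empty character vector of SMILES.
#' @return Scalar in `[0, 1]` with attribute `per_character`.
#' @export
reconstruction_accuracy <- function(model, smiles) {
  stopifnot(inherits(model, "smiles_vae"))
  if (length(smiles) == 0L) stop("empty input list")
  emb <- embed_molecules(model, smiles, mode = "mean")
  decoded_ids <- .greedy_decode(model, emb$posterior_means)
  decoded <- detokenize(decoded_ids, model$vocab)
  exact <- mean(decoded == smiles)
  per_char <- mean(unlist(lapply(seq_along(smiles), function(i) {
    a <- strsplit(smiles[[i]], "")[[1]]
    b <- strsplit(decoded[[i]], "")[[1]]
    m <- max(length(a), length(b))
    length(a) <- m; length(b) <- m
    same <- a == b
    same[is.na(same)] <- FALSE
    same
  })))
  structure(exact, per_character = per_char)
}

# Serialization -------------------------------------------------------------------

#' Save a trained VAE to a directory
#'
#' Writes `config.yaml`, `vocab.json`, `standardization.json` and the
#' learned weights (`weights.rds`).
#'
#' @param model A `smiles_vae`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_vae <- function(model, dir) {
  stopifnot(inherits(model, "smiles_vae"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(model$config), file.path(dir, "config.yaml"))
  jsonlite::write_json(list(tokens = model$vocab$tokens,
                            max_length = model$vocab$max_length),
                       file.path(dir, "vocab.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(
    descriptor_names = model$descriptor_names,
    stats = model$descriptor_stats,
    char_weights = as.list(model$char_weights)),
    file.path(dir, "standardization.json"), auto_unbox = TRUE,
    digits = NA)
  saveRDS(list(params = model$params, history = model$history),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' Load a VAE saved by [save_vae()]
#'
#' @param dir Directory written by [save_vae()].
#' @return A `smiles_vae`.
#' @export
load_vae <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(vae_config, cfg[setdiff(names(cfg), NULL)])
  vj <- jsonlite::read_json(file.path(dir, "vocab.json"),
                            simplifyVector = TRUE)
  vocab <- structure(list(tokens = vj$tokens,
                          token_to_index = stats::setNames(
                            seq_along(vj$tokens), vj$tokens),
                          max_length = as.integer(vj$max_length),
                          pad = 1L, bos = 2L, eos = 3L),
                     class = "vae_vocab")
  sj <- jsonlite::read_json(file.path(dir, "standardization.json"),
                            simplifyVector = TRUE)
  w <- readRDS(file.path(dir, "weights.rds"))
  cw <- if (length(sj$char_weights)) unlist(sj$char_weights) else NULL
  stats_df <- if (is.data.frame(sj$stats)) sj$stats else NULL
  structure(list(config = config, vocab = vocab, params = w$params,
                 descriptor_names = as.character(sj$descriptor_names),
                 descriptor_stats = stats_df, char_weights = cw,
                 history = w$history),
            class = "smiles_vae")
}
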