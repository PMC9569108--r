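# Minimal neural-network toolkit used by the VAEs and the neural QSAR
# families: dense, GRU and 1-D convolution layers with hand-derived
# backpropagation, plus an Adam optimizer. Everything is plain matrix
# algebra on batches; gradients are validated against central differences
# in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.relu <- function(x) pmax(x, 0)

# Glorot-uniform init, seeded by the caller's RNG state
.init_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.zeros <- function(n) numeric(n)

# Dense ------------------------------------------------------------------

dense_init <- function(d_in, d_out) {
  list(W = .init_mat(d_in, d_out), b = .zeros(d_out))
}

dense_forward <- function(X, p) {
  sweep(X %*% p$W, 2, p$b, "+")
}

# returns list(dX, grads = list(W, b))
dense_backward <- function(X, p, dY) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))
}

# GRU --------------------------------------------------------------------
# r_t = sigmoid(X W_xr + h_{t-1} W_hr + b_r)
# u_t = sigmoid(X W_xu + h_{t-1} W_hu + b_u)
# c_t = tanh(X W_xc + (r_t * h_{t-1}) W_hc + b_c)
# h_t = u_t * h_{t-1} + (1 - u_t) * c_t

gru_init <- function(d_in, d_hidden) {
  list(Wxr = .init_mat(d_in, d_hidden), Whr = .init_mat(d_hidden, d_hidden),
       br = .zeros(d_hidden),
       Wxu = .init_mat(d_in, d_hidden), Whu = .init_mat(d_hidden, d_hidden),
       bu = .zeros(d_hidden),
       Wxc = .init_mat(d_in, d_hidden), Whc = .init_mat(d_hidden, d_hidden),
       bc = .zeros(d_hidden))
}

# X_list: list of T matrices (n x d_in); h0: n x H
# returns H_list (length T, h after each step) and per-step caches
gru_forward <- function(X_list, p, h0) {
  T_len <- length(X_list)
  H_list <- vector("list", T_len)
  cache <- vector("list", T_len)
  h <- h0
  for (t in seq_len(T_len)) {
    X <- X_list[[t]]
    r <- .sigmoid(sweep(X %*% p$Wxr + h %*% p$Whr, 2, p$br, "+"))
    u <- .sigmoid(sweep(X %*% p$Wxu + h %*% p$Whu, 2, p$bu, "+"))
    rh <- r * h
    cc <- tanh(sweep(X %*% p$Wxc + rh %*% p$Whc, 2, p$bc, "+"))
    hn <- u * h + (1 - u) * cc
    cache[[t]] <- list(r = r, u = u, cc = cc, rh = rh, h_prev = h)
    H_list[[t]] <- hn
    h <- hn
  }
  list(H_list = H_list, cache = cache)
}

# dH_list: per-step gradients w.r.t. h_t (NULL entries allowed);
# returns parameter grads, dX_list and dh0
gru_backward <- function(X_list, p, fwd, dH_list) {
  T_len <- length(X_list)
  g <- lapply(p, function(m) if (is.matrix(m)) m * 0 else m * 0)
  dX_list <- vector("list", T_len)
  dh <- NULL
  for (t in rev(seq_len(T_len))) {
    ca <- fwd$cache[[t]]
    dcur <- dH_list[[t]]
    if (is.null(dcur)) dcur <- 0
    dh_t <- if (is.null(dh)) dcur else dcur + dh
    if (is.numeric(dh_t) && length(dh_t) == 1L) {
      dX_list[[t]] <- X_list[[t]] * 0
      dh <- NULL
      next
    }
    X <- X_list[[t]]
    du <- dh_t * (ca$h_prev - ca$cc)
    dcc <- dh_t * (1 - ca$u)
    dh_prev <- dh_t * ca$u
    dac <- dcc * (1 - ca$cc^2)
    g$Wxc <- g$Wxc + crossprod(X, dac)
    g$Whc <- g$Whc + crossprod(ca$rh, dac)
    g$bc <- g$bc + colSums(dac)
    drh <- dac %*% t(p$Whc)
    dr <- drh * ca$h_prev
    dh_prev <- dh_prev + drh * ca$r
    dar <- dr * ca$r * (1 - ca$r)
    dau <- du * ca$u * (1 - ca$u)
    g$Wxr <- g$Wxr + crossprod(X, dar)
    g$Whr <- g$Whr + crossprod(ca$h_prev, dar)
    g$br <- g$br + colSums(dar)
    g$Wxu <- g$Wxu + crossprod(X, dau)
    g$Whu <- g$Whu + crossprod(ca$h_prev, dau)
    g$bu <- g$bu + colSums(dau)
    dh_prev <- dh_prev + dar %*% t(p$Whr) + dau %*% t(p$Whu)
    dX_list[[t]] <- dar %*% t(p$Wxr) + dau %*% t(p$Wxu) + dac %*% t(p$Wxc)
    dh <- dh_prev
  }
  list(grads = g, dX_list = dX_list, dh0 = if (is.null(dh)) NULL else dh)
}

# 1-D convolution (same padding, stride 1) --------------------------------
# X: n x T x C_in array; W: K x C_in x C_out; returns n x T x C_out

conv1d_init <- function(k, c_in, c_out) {
  lim <- sqrt(6 / (k * c_in + c_out))
  list(W = array(stats::runif(k * c_in * c_out, -lim, lim),
                 dim = c(k, c_in, c_out)),
       b = .zeros(c_out))
}

# unfold X into (n*T) x (K*C_in) with zero padding
.im2col <- function(X, k) {
  n <- dim(X)[1]; T_len <- dim(X)[2]; c_in <- dim(X)[3]
  pad <- (k - 1L) %/% 2L
  out <- matrix(0, n * T_len, k * c_in)
  for (kk in seq_len(k)) {
    src <- seq_len(T_len) + kk - 1L - pad
    ok <- src >= 1L & src <= T_len
    if (!any(ok)) next
    block <- matrix(0, n * T_len, c_in)
    sl <- X[, src[ok], , drop = FALSE]
    rows <- as.vector(outer(seq_len(n), (which(ok) - 1L) * n, "+"))
    block[rows, ] <- matrix(sl, ncol = c_in)
    out[, ((kk - 1L) * c_in + 1L):(kk * c_in)] <- block
  }
  out
}

conv1d_forward <- function(X, p) {
  n <- dim(X)[1]; T_len <- dim(X)[2]
  k <- dim(p$W)[1]; c_in <- dim(p$W)[2]; c_out <- dim(p$W)[3]
  Xcol <- .im2col(X, k)
  Wmat <- matrix(p$W, k * c_in, c_out)
  Y <- sweep(Xcol %*% Wmat, 2, p$b, "+")
  list(Y = array(Y, dim = c(n, T_len, c_out)), Xcol = Xcol)
}

conv1d_backward <- function(X, p, fwd, dY) {
  n <- dim(X)[1]; T_len <- dim(X)[2]
  k <- dim(p$W)[1]; c_in <- dim(p$W)[2]; c_out <- dim(p$W)[3]
  pad <- (k - 1L) %/% 2L
  dYm <- matrix(dY, n * T_len, c_out)
  Wmat <- matrix(p$W, k * c_in, c_out)
  dW <- array(crossprod(fwd$Xcol, dYm), dim = c(k, c_in, c_out))
  db <- colSums(dYm)
  dXcol <- dYm %*% t(Wmat)
  dX <- array(0, dim = dim(X))
  for (kk in seq_len(k)) {
    src <- seq_len(T_len) + kk - 1L - pad
    ok <- src >= 1L & src <= T_len
    if (!any(ok)) next
    rows <- as.vector(outer(seq_len(n), (which(ok) - 1L) * n, "+"))
    block <- dXcol[rows, ((kk - 1L) * c_in + 1L):(kk * c_in), drop = FALSE]
    dX[, src[ok], ] <- dX[, src[ok], , drop = FALSE] +
      array(block, dim = c(n, sum(ok), c_in))
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

# Adam ---------------------------------------------------------------------

adam_init <- function(params) {
  flat <- .flatten_params(params)
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

.param_keys <- function(params) {
  nms <- names(params)
  if (is.null(nms)) nms <- rep("", length(params))
  ifelse(nzchar(nms), nms, paste0("#", seq_along(params)))
}

.flatten_params <- function(params, prefix = "") {
  out <- list()
  keys <- .param_keys(params)
  for (i in seq_along(params)) {
    p <- params[[i]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", keys[i]) else keys[i]
    if (is.list(p)) {
      out <- c(out, .flatten_params(p, key))
    } else {
      out[[key]] <- p
    }
  }
  out
}

.unflatten_into <- function(params, flat, prefix = "") {
  keys <- .param_keys(params)
  for (i in seq_along(params)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", keys[i]) else keys[i]
    if (is.list(params[[i]])) {
      params[[i]] <- .unflatten_into(params[[i]], flat, key)
    } else {
      params[[i]] <- flat[[key]]
    }
  }
  params
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  fp <- .flatten_params(params)
  fg <- .flatten_params(grads)
  state$t <- state$t + 1L
  for (nm in names(fp)) {
    g <- fg[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    fp[[nm]] <- fp[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = .unflatten_into(params, fp), state = state)
}

# central-difference gradient of scalar f w.r.t. a flat parameter list;
# used only by the test suite as the backprop oracle
numeric_grad <- function(f, params, eps = 1e-5) {
  flat <- .flatten_params(params)
  out <- lapply(flat, function(x) x * 0)
  for (nm in names(flat)) {
    x <- flat[[nm]]
    for (i in seq_along(x)) {
      xp <- flat; xp[[nm]][i] <- x[i] + eps
      xm <- flat; xm[[nm]][i] <- x[i] - eps
      out[[nm]][i] <- (f(.unflatten_into(params, xp)) -
                         f(.unflatten_into(params, xm))) / (2 * eps)
    }
  }
  .unflatten_into(lapply(params, function(p) p), out)
}
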