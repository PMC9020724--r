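# Low-level differentiable layers for the 1D convolutional models.
#
# Activations travel as 3-d arrays (batch n, length L, channels C); dense
# layers use plain (n, features) matrices. Convolutions are evaluated by
# im2col + matrix multiply, which keeps everything inside BLAS. Every
# *_fwd returns what its *_bwd needs; backward passes are verified against
# finite differences in the test suite.

# --- 1D convolution, "same" padding ---------------------------------------
# W is (k * Cin, Cout) with the kernel offset as the slow index: rows
# 1..Cin are offset 1, rows Cin+1..2Cin offset 2, and so on.

conv1d_fwd <- function(X, W, b, k) {
  d <- dim(X); n <- d[1]; L <- d[2]; Cin <- d[3]
  pad_l <- (k - 1L) %/% 2L
  Xp <- array(0, c(n, L + k - 1L, Cin))
  Xp[, pad_l + seq_len(L), ] <- X
  Xcol <- matrix(0, n * L, k * Cin)
  for (j in seq_len(k)) {
    Xcol[, (j - 1L) * Cin + seq_len(Cin)] <-
      matrix(Xp[, j + seq_len(L) - 1L, , drop = FALSE], n * L, Cin)
  }
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = array(Y, c(n, L, ncol(W))), Xcol = Xcol)
}

conv1d_bwd <- function(dY, Xcol, W, k, n, L, Cin) {
  Cout <- ncol(W)
  dYm <- matrix(dY, n * L, Cout)
  dW <- crossprod(Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- tcrossprod(dYm, W)
  pad_l <- (k - 1L) %/% 2L
  dXp <- array(0, c(n, L + k - 1L, Cin))
  for (j in seq_len(k)) {
    dXp[, j + seq_len(L) - 1L, ] <- dXp[, j + seq_len(L) - 1L, , drop = FALSE] +
      array(dXcol[, (j - 1L) * Cin + seq_len(Cin)], c(n, L, Cin))
  }
  list(dX = dXp[, pad_l + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

# --- batch normalization over (batch, position) per channel ----------------

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(X); n <- d[1]; L <- d[2]; C <- d[3]
  Xm <- matrix(X, n * L, C)
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans((Xm - rep(mu, each = nrow(Xm)))^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  m <- nrow(Xm)
  xhat <- (Xm - rep(mu, each = m)) * rep(inv_sd, each = m)
  Y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  list(Y = array(Y, d), cache = list(xhat = xhat, inv_sd = inv_sd, dim = d,
                                     training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dY, cache, gamma) {
  d <- cache$dim; m <- d[1] * d[2]
  dYm <- matrix(dY, m, d[3])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  if (!cache$training) {
    dX <- dYm * rep(gamma * cache$inv_sd, each = m)
    return(list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta))
  }
  dxhat <- dYm * rep(gamma, each = m)
  t1 <- dxhat - rep(colMeans(dxhat), each = m)
  t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = m)
  dX <- (t1 - t2) * rep(cache$inv_sd, each = m)
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# --- pointwise and pooling layers ------------------------------------------

relu_fwd <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  Y
}

relu_bwd <- function(dY, Y) dY * (Y > 0)

avgpool_fwd <- function(X, w, s) {
  d <- dim(X); L <- d[2]
  P <- (L - w) %/% s + 1L
  if (P < 1L) stop_spec("pooling layer: input length ", L,
                        " shorter than window ", w)
  starts <- (seq_len(P) - 1L) * s + 1L
  Y <- array(0, c(d[1], P, d[3]))
  for (j in seq_len(w)) Y <- Y + X[, starts + j - 1L, , drop = FALSE]
  list(Y = Y / w, L = L, P = P)
}

avgpool_bwd <- function(dY, w, s, L) {
  d <- dim(dY)
  starts <- (seq_len(d[2]) - 1L) * s + 1L
  dX <- array(0, c(d[1], L, d[3]))
  for (j in seq_len(w)) {
    idx <- starts + j - 1L
    dX[, idx, ] <- dX[, idx, , drop = FALSE] + dY / w
  }
  dX
}

upsample2_fwd <- function(X) {
  d <- dim(X)
  Y <- array(0, c(d[1], 2L * d[2], d[3]))
  Y[, seq(1L, 2L * d[2], by = 2L), ] <- X
  Y[, seq(2L, 2L * d[2], by = 2L), ] <- X
  Y
}

upsample2_bwd <- function(dY) {
  d <- dim(dY)
  dY[, seq(1L, d[2], by = 2L), , drop = FALSE] +
    dY[, seq(2L, d[2], by = 2L), , drop = FALSE]
}

# --- dense / dropout / heads ----------------------------------------------

dense_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y + rep(b, each = nrow(Y))
}

dense_bwd <- function(dY, X, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- (matrix(stats::runif(length(X)), nrow(X)) >= rate) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Linear interpolation resize as a fixed matrix: maps a length-`from` signal
# onto `to` evenly spaced query points spanning the same support. Used to
# bring the decoder output back onto the input wavelength grid; its
# transpose is the exact gradient.
interp_matrix <- function(from, to) {
  if (from == to) return(diag(from))
  pos <- seq(1, from, length.out = to)
  lo <- pmin(floor(pos), from - 1L)
  whi <- pos - lo
  M <- matrix(0, to, from)
  M[cbind(seq_len(to), lo)] <- 1 - whi
  M[cbind(seq_len(to), lo + 1L)] <- whi
  M
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  lr_t <- lr * sqrt(bc2) / bc1
  eps_t <- eps * sqrt(bc2)
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    v <- state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr_t * m / (sqrt(v) + eps_t)
  }
  list(params = params, state = state)
}
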