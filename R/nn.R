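# Internal neural-network primitives. Sequence activations travel as
# (B * T) x C matrices with the batch index fastest (row b + (t-1) * B holds
# instance b at time step t), so that time shifts, pooling windows and LSTM
# steps are contiguous row-block operations on ordinary matrices and the
# heavy lifting stays inside BLAS. Parameters live in a flat named list so
# the optimizer and the transfer-learning freeze rule can address them by
# name prefix. Every layer has a forward (output + cache) and a backward
# (input gradient + parameter gradients); gradients are verified against
# finite differences in the test suite.

glorot <- function(nrow, ncol) {
  r <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
}

# rows of time step t in the (B * T) x C layout
step_rows <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# Shift a (B * T) x C matrix by `o` time steps (new[t] = old[t + o]),
# zero-filling at the sequence boundary.
time_shift <- function(X, B, T, o) {
  if (o == 0L) return(X)
  C <- ncol(X)
  out <- matrix(0, B * T, C)
  if (o > 0L) {
    out[1:((T - o) * B), ] <- X[(o * B + 1L):(B * T), ]
  } else {
    out[((-o) * B + 1L):(B * T), ] <- X[1:((T + o) * B), ]
  }
  out
}

# add a per-column bias without sweep()'s aperm overhead
add_bias <- function(Y, b) {
  n <- nrow(Y)
  Y + rep.int(b, rep.int(n, length(b)))
}

## ---- 1D convolution (same padding, odd kernel) ----

# X: (B*T) x Cin; W: (Cin * k) x Cout; b: Cout
conv1d_forward <- function(X, W, b, k, B, T) {
  half <- (k - 1L) %/% 2L
  Cin <- ncol(X)
  Xcol <- matrix(0, B * T, Cin * k)
  for (j in seq_len(k)) {
    o <- j - half - 1L
    cols <- ((j - 1L) * Cin + 1L):(j * Cin)
    if (o == 0L) {
      Xcol[, cols] <- X
    } else if (o > 0L) {
      Xcol[1:((T - o) * B), cols] <- X[(o * B + 1L):(B * T), ]
    } else {
      Xcol[((-o) * B + 1L):(B * T), cols] <- X[1:((T + o) * B), ]
    }
  }
  Y <- add_bias(Xcol %*% W, b)
  list(out = Y, cache = list(Xcol = Xcol, k = k, B = B, T = T, Cin = Cin))
}

conv1d_backward <- function(dY, W, cache) {
  k <- cache$k; B <- cache$B; T <- cache$T; Cin <- cache$Cin
  half <- (k - 1L) %/% 2L
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)
  dX <- matrix(0, B * T, Cin)
  for (j in seq_len(k)) {
    block <- dXcol[, ((j - 1L) * Cin + 1L):(j * Cin), drop = FALSE]
    dX <- dX + time_shift(block, B, T, -(j - half - 1L))
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- ReLU ----

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

relu_backward <- function(dY, mask) dY * mask

## ---- Non-overlapping max pooling along time ----

pool_rows <- function(j, p, B, Tout) {
  # rows of time steps (tout-1)*p + j for tout = 1..Tout
  as.vector(outer(1:B, ((0:(Tout - 1L)) * p + (j - 1L)) * B, "+"))
}

# In training mode the argmax per pooling window is cached for the backward
# pass; in inference mode a cheaper pmax scan suffices.
maxpool_forward <- function(X, p, B, T, train = FALSE) {
  Tout <- T %/% p
  M <- X[pool_rows(1L, p, B, Tout), , drop = FALSE]
  if (!train) {
    if (p > 1L) {
      for (j in 2:p) M <- pmax(M, X[pool_rows(j, p, B, Tout), , drop = FALSE])
    }
    return(list(out = M, cache = NULL))
  }
  idx <- matrix(1L, nrow(M), ncol(M))
  if (p > 1L) {
    for (j in 2:p) {
      cand <- X[pool_rows(j, p, B, Tout), , drop = FALSE]
      upd <- cand > M
      M[upd] <- cand[upd]
      idx[upd] <- j
    }
  }
  list(out = M, cache = list(idx = idx, p = p, B = B, T = T, Tout = Tout))
}

maxpool_backward <- function(dY, cache) {
  p <- cache$p; B <- cache$B; Tout <- cache$Tout
  dX <- matrix(0, B * cache$T, ncol(dY))
  for (j in seq_len(p)) {
    dX[pool_rows(j, p, B, Tout), ] <- dY * (cache$idx == j)
  }
  dX
}

## ---- LSTM (single direction) ----

# X: (B*T) x D; Wx: D x 4H; Wh: H x 4H; b: 4H. Gate order: i, f, o, g —
# the three sigmoid gates are contiguous so one exp() covers them all.
lstm_forward <- function(X, Wx, Wh, b, B, T, reverse = FALSE) {
  D <- ncol(X)
  H <- ncol(Wx) %/% 4L
  order <- if (reverse) T:1 else 1:T
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  Hs <- matrix(0, B * T, H)
  steps <- vector("list", T)
  sig_cols <- 1:(3L * H)
  gg <- (3L * H + 1L):(4L * H)
  for (s in seq_len(T)) {
    t <- order[s]
    rows <- step_rows(t, B)
    Xt <- X[rows, , drop = FALSE]
    Z <- add_bias(Xt %*% Wx + h %*% Wh, b)
    S <- 1 / (1 + exp(-Z[, sig_cols, drop = FALSE]))
    i_g <- S[, 1:H, drop = FALSE]
    f_g <- S[, (H + 1L):(2L * H), drop = FALSE]
    o_g <- S[, (2L * H + 1L):(3L * H), drop = FALSE]
    g_g <- tanh(Z[, gg, drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    tc <- tanh(c_new)
    steps[[s]] <- list(rows = rows, Xt = Xt, h_prev = h, c_prev = cc,
                       i = i_g, f = f_g, g = g_g, o = o_g, tc = tc)
    h <- o_g * tc
    cc <- c_new
    Hs[rows, ] <- h
  }
  list(out = Hs, last_h = h,
       cache = list(steps = steps, B = B, T = T, D = D, H = H))
}

# dH: (B*T) x H gradient on per-step outputs (may be all-zero);
# dlast: optional (B x H) gradient on the final hidden state.
lstm_backward <- function(dH, Wx, Wh, cache, dlast = NULL) {
  B <- cache$B; T <- cache$T; D <- cache$D; H <- cache$H
  dWx <- matrix(0, D, 4L * H)
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- matrix(0, B * T, D)
  dh_next <- if (is.null(dlast)) matrix(0, B, H) else dlast
  dc_next <- matrix(0, B, H)
  tWx <- t(Wx)
  tWh <- t(Wh)
  for (s in T:1) {
    st <- cache$steps[[s]]
    dh <- dH[st$rows, , drop = FALSE] + dh_next
    do_g <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_g * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dWx <- dWx + crossprod(st$Xt, dZ)
    dWh <- dWh + crossprod(st$h_prev, dZ)
    db <- db + colSums(dZ)
    dX[st$rows, ] <- dZ %*% tWx
    dh_next <- dZ %*% tWh
    dc_next <- dc * st$f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

## ---- Additive (Bahdanau-style) attention over time steps ----

# H: (B*T) x M; Wa: M x A; va: A. Returns context (B x M).
attention_forward <- function(H, Wa, va, B, T) {
  M <- ncol(H)
  U <- tanh(H %*% Wa)
  s <- matrix(U %*% va, B, T)
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  alpha <- e / rowSums(e)
  ctx <- matrix(0, B, M)
  for (t in seq_len(T)) {
    ctx <- ctx + alpha[, t] * H[step_rows(t, B), , drop = FALSE]
  }
  list(out = ctx, alpha = alpha,
       cache = list(U = U, alpha = alpha, B = B, T = T))
}

attention_backward <- function(dctx, H, Wa, va, cache) {
  B <- cache$B; T <- cache$T
  M <- ncol(H)
  alpha <- cache$alpha
  dH <- matrix(0, B * T, M)
  dalpha <- matrix(0, B, T)
  for (t in seq_len(T)) {
    rows <- step_rows(t, B)
    Ht <- H[rows, , drop = FALSE]
    dH[rows, ] <- alpha[, t] * dctx
    dalpha[, t] <- rowSums(dctx * Ht)
  }
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))
  ds_flat <- as.vector(ds)
  dU <- outer(ds_flat, va)
  dpre <- dU * (1 - cache$U^2)
  dWa <- crossprod(H, dpre)
  dva <- as.vector(crossprod(cache$U, ds_flat))
  dH <- dH + dpre %*% t(Wa)
  list(dH = dH, dWa = dWa, dva = dva)
}

## ---- Dense, dropout ----

dense_forward <- function(X, W, b) {
  list(out = add_bias(X %*% W, b), cache = X)
}

dense_backward <- function(dY, W, X) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# Inverted dropout; identity when rate == 0 or not training.
dropout_forward <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, cache = NULL))
  mask <- (stats::runif(length(X)) > rate) / (1 - rate)
  dim(mask) <- dim(X)
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

## ---- Weighted softmax cross-entropy ----

#' Softmax probabilities from logits
#'
#' Numerically stable softmax; invariant to adding a constant to all logits.
#'
#' @param logits Numeric vector, or matrix with one row per observation.
#' @return Probabilities of the same shape; each row is positive and sums to 1.
#' @examples
#' softmax_prob(c(log(3), 0))  # 0.75 0.25
#' @export
softmax_prob <- function(logits) {
  if (any(!is.finite(logits))) stop("non-finite logits", call. = FALSE)
  if (is.null(dim(logits))) {
    z <- logits - max(logits)
    e <- exp(z)
    return(e / sum(e))
  }
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class-weighted cross-entropy loss
#'
#' The loss for one observation with label `y` is `-w[y] * log softmax(z)[y]`;
#' the batch loss is the weight-normalized mean, `sum(w[y_i] * nll_i) /
#' sum(w[y_i])`. Equal weights give the plain mean negative log-likelihood.
#'
#' @param logits Matrix (n x C) of raw model outputs.
#' @param y Integer class labels in `1..C`.
#' @param class_weights Positive weight per class (default equal).
#' @return List with `loss` (scalar) and `grad` (n x C gradient wrt logits).
#' @export
cross_entropy_loss <- function(logits, y, class_weights = NULL) {
  n <- nrow(logits)
  C <- ncol(logits)
  if (is.null(class_weights)) class_weights <- rep(1, C)
  if (length(class_weights) != C || any(class_weights <= 0)) {
    stop("`class_weights` must be positive, one per class", call. = FALSE)
  }
  p <- softmax_prob(logits)
  sel <- cbind(seq_len(n), y)
  w <- class_weights[y]
  wsum <- sum(w)
  loss <- sum(-w * log(pmax(p[sel], 1e-300))) / wsum
  grad <- p
  grad[sel] <- grad[sel] - 1
  grad <- grad * (w / wsum)
  list(loss = loss, grad = grad)
}
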