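# Bidirectional LSTM branch for the 1-s morphology segment.
#
# Two bidirectional layers with 25 hidden units per direction, so that the
# concatenated feature width is the stated 50: layer 1 returns the full
# sequence, a 0.5 dropout sits between the layers, layer 2 returns only its
# last step (forward direction at t = T, backward direction at t = 1), and a
# 50 -> 2 dense + softmax head closes the standalone classifier.

lstm_init <- function(d_in, hidden) {
  s <- 1 / sqrt(hidden)
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1   # forget-gate bias at 1
  list(Wx = matrix(rnorm(d_in * 4 * hidden, 0, s), d_in, 4 * hidden),
       Wh = matrix(rnorm(hidden * 4 * hidden, 0, s), hidden, 4 * hidden),
       b = b)
}

# X: B x T x D array. Returns the full hidden sequence (B x T x H) plus the
# per-step cache needed for BPTT.
lstm_forward <- function(X, p) {
  b <- dim(X)[1]; tt <- dim(X)[2]
  hdim <- ncol(p$Wh)
  hh <- hdim %/% 4
  h <- matrix(0, b, hh)
  cc <- matrix(0, b, hh)
  out <- array(0, dim = c(b, tt, hh))
  cache <- vector("list", tt)
  for (t in seq_len(tt)) {
    x_t <- matrix(X[, t, ], b)
    z <- x_t %*% p$Wx + h %*% p$Wh + rep(p$b, each = b)
    i <- sigmoid(z[, 1:hh, drop = FALSE])
    f <- sigmoid(z[, (hh + 1):(2 * hh), drop = FALSE])
    g <- tanh(z[, (2 * hh + 1):(3 * hh), drop = FALSE])
    o <- sigmoid(z[, (3 * hh + 1):(4 * hh), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    out[, t, ] <- h
    cache[[t]] <- list(x = x_t, h_prev = h_prev, c_prev = c_prev,
                       i = i, f = f, g = g, o = o, tc = tc)
  }
  list(out = out, cache = cache)
}

# dout: B x T x H gradient on the hidden sequence (zero-filled except the
# last step when only that step is consumed downstream).
lstm_backward <- function(dout, cache, p) {
  b <- dim(dout)[1]; tt <- dim(dout)[2]; hh <- dim(dout)[3]
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dh <- matrix(0, b, hh)
  dc <- matrix(0, b, hh)
  dX <- array(0, dim = c(b, tt, nrow(p$Wx)))
  for (t in rev(seq_len(tt))) {
    ca <- cache[[t]]
    dh <- dh + matrix(dout[, t, ], b)
    do_ <- dh * ca$tc
    dc <- dc + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g
    dg <- dc * ca$i
    df <- dc * ca$c_prev
    dz <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do_ * ca$o * (1 - ca$o))
    dWx <- dWx + t(ca$x) %*% dz
    dWh <- dWh + t(ca$h_prev) %*% dz
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(p$Wx)
    dh <- dz %*% t(p$Wh)
    dc <- dc * ca$f
  }
  list(dx = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

reverse_time <- function(X) {
  X[, rev(seq_len(dim(X)[2])), , drop = FALSE]
}

# Bidirectional layer: forward pass on X plus a forward pass on time-reversed
# X; outputs are concatenated on the feature axis in original time order.
bilstm_layer_forward <- function(X, pf, pb) {
  fwd <- lstm_forward(X, pf)
  bwd <- lstm_forward(reverse_time(X), pb)
  out <- array(0, dim = c(dim(X)[1], dim(X)[2],
                          dim(fwd$out)[3] + dim(bwd$out)[3]))
  out[, , seq_len(dim(fwd$out)[3])] <- fwd$out
  out[, , -seq_len(dim(fwd$out)[3])] <- reverse_time(bwd$out)
  list(out = out, cache = list(fwd = fwd$cache, bwd = bwd$cache,
                               hf = dim(fwd$out)[3]))
}

bilstm_layer_backward <- function(dout, cache, pf, pb) {
  hf <- cache$hf
  df <- lstm_backward(dout[, , seq_len(hf), drop = FALSE], cache$fwd, pf)
  db <- lstm_backward(reverse_time(dout[, , -seq_len(hf), drop = FALSE]),
                      cache$bwd, pb)
  list(dx = df$dx + reverse_time(db$dx),
       grads = list(f = df$grads, b = db$grads))
}

bilstm_init <- function(input_dim = 1, hidden = 25, feature_dim = 2 * hidden) {
  list(l1f = lstm_init(input_dim, hidden),
       l1b = lstm_init(input_dim, hidden),
       l2f = lstm_init(2 * hidden, hidden),
       l2b = lstm_init(2 * hidden, hidden),
       head = dense_init(feature_dim, 2, scale = 0))
}

#' Forward pass of the Bi-LSTM morphology branch
#'
#' @param X B x 125 matrix of 1-s segments (or a single numeric vector).
#' @param w Branch weights from the model initialiser.
#' @param train Logical; activates the inter-layer dropout.
#' @param dropout_p Dropout probability between the two recurrent layers.
#' @return List with `feature` (B x 50 last-step output of the second
#'   bidirectional layer), `probs` (B x 2 softmax of the standalone head)
#'   and `cache` for backprop.
#' @keywords internal
bilstm_forward <- function(X, w, train = FALSE, dropout_p = 0.5) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  b <- nrow(X); tt <- ncol(X)
  X3 <- array(X, dim = c(b, tt, 1))
  l1 <- bilstm_layer_forward(X3, w$l1f, w$l1b)
  dr <- dropout_forward(l1$out, dropout_p, train)
  l2 <- bilstm_layer_forward(dr$out, w$l2f, w$l2b)
  hf <- l2$cache$hf
  # last step of each direction: forward at t = T, backward at t = 1
  feature <- cbind(matrix(l2$out[, tt, seq_len(hf)], b),
                   matrix(l2$out[, 1, -seq_len(hf)], b))
  hd <- dense_forward(feature, w$head)
  probs <- softmax_rows(hd$out)
  list(feature = feature, probs = probs,
       cache = list(l1 = l1$cache, dr = dr$cache, l2 = l2$cache,
                    head = hd$cache, tt = tt, b = b, hf = hf,
                    dims = dim(l2$out)))
}

# dfeat: B x 50 gradient on the feature; dlogits: optional B x 2 gradient on
# the head logits (standalone training).
bilstm_backward <- function(dfeat, cache, w, dlogits = NULL) {
  grads <- list()
  if (!is.null(dlogits)) {
    hd <- dense_backward(dlogits, cache$head, w$head)
    grads$head <- hd$grads
    dfeat <- dfeat + hd$dx
  }
  hf <- cache$hf
  dseq <- array(0, dim = cache$dims)
  dseq[, cache$tt, seq_len(hf)] <- dfeat[, seq_len(hf)]
  dseq[, 1, -seq_len(hf)] <- dfeat[, -seq_len(hf), drop = FALSE]
  l2 <- bilstm_layer_backward(dseq, cache$l2, w$l2f, w$l2b)
  ddr <- dropout_backward(l2$dx, cache$dr)
  l1 <- bilstm_layer_backward(ddr, cache$l1, w$l1f, w$l1b)
  grads$l2f <- l2$grads$f; grads$l2b <- l2$grads$b
  grads$l1f <- l1$grads$f; grads$l1b <- l1$grads$b
  grads
}
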