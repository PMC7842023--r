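# Low-level neural-network layers with hand-written backpropagation.
#
# Conventions: 1-D feature maps are L x C matrices (time by channel); 2-D
# maps are H x W x C arrays; dense activations are B x D matrices. Every
# forward returns list(out, cache); every backward takes (dout, cache) and
# returns list(dx, grads). Parameters live in plain named lists so a whole
# model is one nested list that the Adam updater walks generically.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(dout, x) {
  dout * (x > 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with the usual max-shift for stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy of B x K probabilities against integer labels 1..K,
# with its gradient wrt the pre-softmax logits.
cross_entropy <- function(probs, y) {
  b <- nrow(probs)
  p <- pmax(probs[cbind(seq_len(b), y)], 1e-12)
  loss <- -mean(log(p))
  dlogits <- probs
  dlogits[cbind(seq_len(b), y)] <- dlogits[cbind(seq_len(b), y)] - 1
  list(loss = loss, dlogits = dlogits / b)
}

# Dense ----------------------------------------------------------------------

dense_init <- function(d_in, d_out, scale = sqrt(2 / d_in)) {
  list(W = matrix(rnorm(d_in * d_out, 0, scale), d_in, d_out),
       b = numeric(d_out))
}

dense_forward <- function(x, p) {
  out <- x %*% p$W
  out <- out + rep(p$b, each = nrow(out))
  list(out = out, cache = x)
}

dense_backward <- function(dout, cache, p) {
  list(dx = tcrossprod(dout, p$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

# 1-D convolution, 'same' padding, stride 1 ----------------------------------

conv1d_init <- function(c_in, c_out, k = 9) {
  scale <- sqrt(2 / (c_in * k))
  list(W = array(rnorm(k * c_in * c_out, 0, scale), dim = c(c_in, c_out, k)),
       b = numeric(c_out), k = k)
}

conv1d_forward <- function(x, p) {
  l <- nrow(x)
  k <- p$k
  pl <- (k - 1) %/% 2
  xp <- rbind(matrix(0, pl, ncol(x)), x, matrix(0, k - 1 - pl, ncol(x)))
  out <- matrix(0, l, dim(p$W)[2])
  for (ki in seq_len(k)) {
    out <- out + xp[ki:(ki + l - 1), , drop = FALSE] %*% p$W[, , ki]
  }
  out <- out + rep(p$b, each = l)
  list(out = out, cache = xp)
}

conv1d_backward <- function(dout, cache, p) {
  xp <- cache
  l <- nrow(dout)
  k <- p$k
  pl <- (k - 1) %/% 2
  dW <- array(0, dim = dim(p$W))
  dxp <- matrix(0, nrow(xp), ncol(xp))
  for (ki in seq_len(k)) {
    rows <- ki:(ki + l - 1)
    dW[, , ki] <- crossprod(xp[rows, , drop = FALSE], dout)
    dxp[rows, ] <- dxp[rows, ] + tcrossprod(dout, p$W[, , ki])
  }
  list(dx = dxp[(pl + 1):(pl + l), , drop = FALSE],
       grads = list(W = dW, b = colSums(dout)))
}

# 2-D convolution, 'same' padding, stride 1; x is H x W x Cin ----------------

conv2d_init <- function(c_in, c_out, k = 9) {
  scale <- sqrt(2 / (c_in * k * k))
  list(W = array(rnorm(k * k * c_in * c_out, 0, scale),
                 dim = c(c_in, c_out, k, k)),
       b = numeric(c_out), k = k)
}

conv2d_forward <- function(x, p) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  k <- p$k
  pl <- (k - 1) %/% 2
  xp <- array(0, dim = c(h + k - 1, w + k - 1, cin))
  xp[pl + seq_len(h), pl + seq_len(w), ] <- x
  cout <- dim(p$W)[2]
  out <- matrix(0, h * w, cout)
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      slab <- matrix(xp[ki:(ki + h - 1), kj:(kj + w - 1), ], h * w, cin)
      out <- out + slab %*% p$W[, , ki, kj]
    }
  }
  out <- out + rep(p$b, each = h * w)
  list(out = array(out, dim = c(h, w, cout)), cache = xp)
}

conv2d_backward <- function(dout, cache, p) {
  xp <- cache
  h <- dim(dout)[1]; w <- dim(dout)[2]; cout <- dim(dout)[3]
  k <- p$k
  pl <- (k - 1) %/% 2
  cin <- dim(xp)[3]
  dmat <- matrix(dout, h * w, cout)
  dW <- array(0, dim = dim(p$W))
  dxp <- array(0, dim = dim(xp))
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      ri <- ki:(ki + h - 1); rj <- kj:(kj + w - 1)
      slab <- matrix(xp[ri, rj, ], h * w, cin)
      dW[, , ki, kj] <- crossprod(slab, dmat)
      dxp[ri, rj, ] <- dxp[ri, rj, ] +
        array(tcrossprod(dmat, p$W[, , ki, kj]), dim = c(h, w, cin))
    }
  }
  list(dx = dxp[pl + seq_len(h), pl + seq_len(w), , drop = FALSE],
       grads = list(W = dW, b = colSums(dmat)))
}

# Max pooling over rows of an L x C matrix (floor division) ------------------

maxpool1d_forward <- function(x, size = 3) {
  l <- nrow(x); cc <- ncol(x)
  lo <- l %/% size
  idx1 <- seq(1, by = size, length.out = lo)
  best <- x[idx1, , drop = FALSE]
  arg <- matrix(1L, lo, cc)
  for (s in 2:size) {
    cand <- x[idx1 + s - 1, , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- s
  }
  list(out = best, cache = list(arg = arg, l = l, size = size, idx1 = idx1))
}

maxpool1d_backward <- function(dout, cache) {
  lo <- nrow(dout); cc <- ncol(dout)
  dx <- matrix(0, cache$l, cc)
  rows <- matrix(cache$idx1, lo, cc) + cache$arg - 1L
  lin <- as.vector(rows) + rep((seq_len(cc) - 1L) * cache$l, each = lo)
  dx[lin] <- as.vector(dout)
  dx
}

# (3, 1) pooling for H x W x C arrays: pool heights only, via the 1-D code.
maxpool2d_rows_forward <- function(x, size = 3) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  r <- maxpool1d_forward(matrix(x, h, w * cc), size)
  list(out = array(r$out, dim = c(h %/% size, w, cc)),
       cache = c(r$cache, list(w = w, cc = cc)))
}

maxpool2d_rows_backward <- function(dout, cache) {
  ho <- dim(dout)[1]
  dx <- maxpool1d_backward(matrix(dout, ho, cache$w * cache$cc), cache)
  array(dx, dim = c(cache$l, cache$w, cache$cc))
}

# Inverted dropout -----------------------------------------------------------

dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) {
    return(list(out = x, cache = NULL))
  }
  mask <- (runif(length(x)) >= p) / (1 - p)
  if (is.matrix(x)) mask <- matrix(mask, nrow(x), ncol(x))
  if (is.array(x) && !is.matrix(x)) mask <- array(mask, dim = dim(x))
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# Adam over an arbitrary nested parameter list -------------------------------

tree_zero <- function(p) {
  if (is.list(p)) lapply(p, tree_zero)
  else if (is.numeric(p)) p * 0
  else p
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 5e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    m_new <- beta1 * m + (1 - beta1) * g
    v_new <- beta2 * v + (1 - beta2) * g^2
    mhat <- m_new / (1 - beta1^state$t)
    vhat <- v_new / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m_new, v = v_new)
  }
  walk <- function(p, g, m, v) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, m = m, v = v))
      return(upd(p, g, m, v))
    }
    out_p <- p; out_m <- m; out_v <- v
    for (nm in names(p)) {
      r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# Sum two gradient trees (for minibatch accumulation).
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (nm in names(a)) out[[nm]] <- tree_add(a[[nm]], b[[nm]])
  out
}

tree_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(a * s)
  lapply(a, tree_scale, s = s)
}

# Batched convolution in channel-major layout --------------------------------
#
# Activations are C x (B*L) matrices (positions sample-major along columns),
# so im2col gathers copy whole contiguous columns and each layer is a single
# wide GEMM. The position-index geometry is memoised per (B, L, k).

.conv_geom <- new.env(parent = emptyenv())

conv_geometry <- function(b, l, k) {
  key <- paste(b, l, k, sep = "_")
  g <- .conv_geom[[key]]
  if (is.null(g)) {
    lp <- l + k - 1
    pl <- (k - 1) %/% 2
    pad_idx <- as.vector(outer(pl + seq_len(l), (0:(b - 1)) * lp, "+"))
    rows_k <- lapply(seq_len(k), function(ki) {
      as.vector(outer(ki:(ki + l - 1), (0:(b - 1)) * lp, "+"))
    })
    g <- list(lp = lp, pad_idx = pad_idx, rows_k = rows_k)
    .conv_geom[[key]] <- g
  }
  g
}

conv1d_forward_batch <- function(x_all, p, b, l) {
  k <- p$k
  g <- conv_geometry(b, l, k)
  cin <- nrow(x_all)
  cout <- dim(p$W)[2]
  xp <- matrix(0, cin, b * g$lp)
  xp[, g$pad_idx] <- x_all
  x2 <- matrix(0, cin * k, b * l)
  for (ki in seq_len(k)) {
    x2[(ki - 1) * cin + seq_len(cin), ] <- xp[, g$rows_k[[ki]], drop = FALSE]
  }
  w2t <- t(matrix(aperm(p$W, c(1, 3, 2)), cin * k, cout))
  out <- w2t %*% x2 + p$b
  list(out = out, cache = x2)
}

# The input gradient of a 'same' stride-1 convolution is itself a 'same'
# convolution of the output gradient with the kernel flipped and its
# channel axes swapped, so the backward pass reuses the forward machinery
# instead of a strided scatter-add.
conv1d_backward_batch <- function(dout, cache, p, b, l, need_dx = TRUE) {
  k <- p$k
  x2 <- cache
  cin <- dim(p$W)[1]
  cout <- dim(p$W)[2]
  dW2 <- tcrossprod(dout, x2)                     # cout x (cin*k)
  dW <- aperm(array(t(dW2), dim = c(cin, k, cout)), c(1, 3, 2))
  dx <- NULL
  if (need_dx) {
    w_rev <- aperm(p$W[, , k:1, drop = FALSE], c(2, 1, 3))
    dx <- conv1d_forward_batch(dout, list(W = w_rev, b = numeric(cin), k = k),
                               b, l)$out
  }
  list(dx = dx, grads = list(W = dW, b = rowSums(dout)))
}

# Max pooling over positions of a channel-major C x (B*L) stack.

.pool_geom <- new.env(parent = emptyenv())

pool_geometry <- function(b, l, size) {
  key <- paste(b, l, size, sep = "_")
  g <- .pool_geom[[key]]
  if (is.null(g)) {
    lo <- l %/% size
    base <- as.vector(outer(seq(1, by = size, length.out = lo),
                            (0:(b - 1)) * l, "+"))
    g <- list(lo = lo, base = base)
    .pool_geom[[key]] <- g
  }
  g
}

maxpool_cm_forward <- function(x, b, l, size = 3) {
  g <- pool_geometry(b, l, size)
  best <- x[, g$base, drop = FALSE]
  arg <- matrix(1L, nrow(x), length(g$base))
  for (s in 2:size) {
    cand <- x[, g$base + s - 1, drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- s
  }
  list(out = best, cache = list(arg = arg, b = b, l = l, size = size))
}

maxpool_cm_backward <- function(dout, cache) {
  g <- pool_geometry(cache$b, cache$l, cache$size)
  cc <- nrow(dout)
  dx <- matrix(0, cc, cache$b * cache$l)
  cols <- matrix(g$base, cc, length(g$base), byrow = TRUE) + cache$arg - 1L
  dx[as.vector((cols - 1L) * cc + seq_len(cc))] <- as.vector(dout)
  dx
}
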