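# Attention layers inserted between the fused flatten vector and the
# classifier head: a chunked self-attention (SAM) and a convolutional block
# attention module (CBAM) whose channel and spatial gates pool by average,
# maximum and stochastic pooling. Both layers preserve vector length.

#' Stochastic pooling of a region of non-negative activations
#'
#' Activations are weighted by their normalised magnitudes
#' `p_i = a_i / sum(a)`. In training mode one activation is sampled with
#' probability `p_i`; in evaluation mode the expectation `sum(p_i a_i)` is
#' returned, so evaluation is deterministic. An all-zero region pools to 0.
#'
#' @param region Numeric vector of non-negative activations.
#' @param mode `"eval"` or `"train"`.
#' @param seed Optional integer seed for the training-mode draw.
#' @return A single pooled value.
#' @export
#' @examples
#' stochastic_pool(c(1, 3), "eval") # 0.25 * 1 + 0.75 * 3 = 2.5
stochastic_pool <- function(region, mode = c("eval", "train"), seed = NULL) {
  mode <- match.arg(mode)
  check_numeric_vector(region, "region")
  if (any(region < -1e-12)) {
    abort("Stochastic pooling requires non-negative activations (post-ReLU).",
          class = "bcgaf_contract_error")
  }
  s <- sum(region)
  if (s <= 0) return(0)
  if (mode == "eval") {
    sum(region^2) / s
  } else {
    draw <- function() sample.int(length(region), 1, prob = region / s)
    k <- if (is.null(seed)) draw() else local_seed_eval(seed, draw())
    region[k]
  }
}

# Row-wise (margin = 1) or column-wise (margin = 2) stochastic pooling of a
# non-negative matrix, with the info needed for backprop.
sto_pool_margin <- function(f, margin, train) {
  if (margin == 2) {
    r <- sto_pool_margin(t(f), 1, train)
    r$margin <- 2
    return(r)
  }
  s1 <- rowSums(f)
  if (train) {
    idx <- integer(nrow(f))
    val <- numeric(nrow(f))
    for (i in seq_len(nrow(f))) {
      if (s1[i] > 0) {
        idx[i] <- sample.int(ncol(f), 1, prob = f[i, ] / s1[i])
        val[i] <- f[i, idx[i]]
      }
    }
    list(value = val, train = TRUE, idx = idx, margin = 1)
  } else {
    s2 <- rowSums(f^2)
    val <- ifelse(s1 > 0, s2 / pmax(s1, 1e-300), 0)
    list(value = val, train = FALSE, s1 = s1, s2 = s2, margin = 1)
  }
}

# Gradient of the pooled values wrt the matrix entries.
sto_pool_margin_backward <- function(dval, info, f) {
  if (info$margin == 2) {
    info$margin <- 1
    return(t(sto_pool_margin_backward(dval, info, t(f))))
  }
  g <- matrix(0, nrow(f), ncol(f))
  if (info$train) {
    ok <- info$idx > 0
    g[cbind(which(ok), info$idx[ok])] <- dval[ok]
  } else {
    ok <- info$s1 > 0
    if (any(ok)) {
      g[ok, ] <- (2 * f[ok, , drop = FALSE] * info$s1[ok] - info$s2[ok]) /
        info$s1[ok]^2 * dval[ok]
    }
  }
  g
}

row_max_backward <- function(dval, f) {
  g <- matrix(0, nrow(f), ncol(f))
  g[cbind(seq_len(nrow(f)), max.col(f, ties.method = "first"))] <- dval
  g
}

# SAM ------------------------------------------------------------------------

#' Initialise self-attention (SAM) weights for a fused vector of length L
#'
#' The vector is split into chunks of length `T = ceiling(sqrt(L))`
#' (zero-padded to `n * T` with `n = ceiling(L / T)` chunks) that are stacked
#' as rows; shared `T x T` query/key/value maps act on the rows.
#'
#' @param L Fused feature length (>= 4).
#' @param d Softmax scaling constant (the dot products are divided by
#'   `sqrt(d)`); fixed at 100.
#' @return SAM weight list with `W_Q`, `W_K`, `W_V`, `T`, `n`, `L`, `d`.
#' @export
sam_init <- function(L, d = 100) {
  check_scalar(L, "L", lower = 4)
  tt <- ceiling(sqrt(L))
  n <- ceiling(L / tt)
  s <- 1 / sqrt(tt)
  list(W_Q = matrix(rnorm(tt * tt, 0, s), tt, tt),
       W_K = matrix(rnorm(tt * tt, 0, s), tt, tt),
       W_V = matrix(rnorm(tt * tt, 0, s), tt, tt),
       T = tt, n = n, L = L, d = d)
}

sam_fwd <- function(x, w) {
  if (any(!is.finite(x))) {
    abort("Non-finite input to the SAM layer.", class = "bcgaf_numeric_error")
  }
  xpad <- c(x, numeric(w$n * w$T - length(x)))
  xr <- matrix(xpad, w$n, w$T, byrow = TRUE)
  zq <- xr %*% w$W_Q; q <- relu(zq)
  zk <- xr %*% w$W_K; k <- relu(zk)
  zv <- xr %*% w$W_V; v <- relu(zv)
  slog <- q %*% t(k) / sqrt(w$d)
  s <- softmax_rows(slog)
  a <- s %*% v
  out <- as.vector(t(a))[seq_len(w$L)]
  list(out = out,
       cache = list(xr = xr, zq = zq, zk = zk, zv = zv, q = q, k = k, v = v,
                    s = s))
}

sam_bwd <- function(dout, cache, w) {
  da <- matrix(c(dout, numeric(w$n * w$T - length(dout))), w$n, w$T,
               byrow = TRUE)
  ds <- da %*% t(cache$v)
  dv <- t(cache$s) %*% da
  # softmax rows backward
  dslog <- cache$s * (ds - rowSums(ds * cache$s))
  dq <- dslog %*% cache$k / sqrt(w$d)
  dk <- t(dslog) %*% cache$q / sqrt(w$d)
  dzq <- dq * (cache$zq > 0)
  dzk <- dk * (cache$zk > 0)
  dzv <- dv * (cache$zv > 0)
  dxr <- dzq %*% t(w$W_Q) + dzk %*% t(w$W_K) + dzv %*% t(w$W_V)
  list(dx = as.vector(t(dxr))[seq_len(w$L)],
       grads = list(W_Q = t(cache$xr) %*% dzq,
                    W_K = t(cache$xr) %*% dzk,
                    W_V = t(cache$xr) %*% dzv))
}

#' Apply the SAM layer to a fused feature vector
#'
#' Chunks the vector, applies ReLU query/key/value projections, row-wise
#' scaled-dot-product softmax attention (`softmax(Q' K'^T / sqrt(d))`), and
#' flattens the attended rows back to the original length.
#'
#' @param x Numeric vector of length `weights$L`.
#' @param weights From [sam_init()].
#' @return Vector of the same length as `x`.
#' @export
sam_layer <- function(x, weights) {
  sam_fwd(x, weights)$out
}

# CBAM -----------------------------------------------------------------------

#' Initialise CBAM weights for a fused vector of length L
#'
#' The flat vector is reshaped (column-major, zero-padded) to a `C x L'`
#' feature map. The channel gate pools each channel over the spatial axis by
#' average, max and stochastic pooling, passes the three `C`-vectors through
#' a shared bottleneck MLP (`C -> C/r -> C`), sums and squashes them through
#' a sigmoid. The spatial gate pools across channels, convolves the spliced
#' 3-channel map with a length-7 filter and squashes through a sigmoid.
#'
#' @param L Fused feature length.
#' @param C Number of channels of the reshaped map.
#' @param r Channel-reduction ratio; must divide `C`.
#' @return CBAM weight list.
#' @export
cbam_init <- function(L, C = 32, r = 8) {
  check_scalar(L, "L", lower = C)
  if (r >= C || C %% r != 0) {
    abort("Reduction `r` must divide `C` and be smaller than it.",
          class = "bcgaf_parameter_error")
  }
  lp <- ceiling(L / C)
  if (lp < 7) {
    abort("Spatial extent shorter than the length-7 filter.",
          class = "bcgaf_parameter_error")
  }
  cr <- C %/% r
  # the expansion map and the spatial filter start at zero so both gates
  # open at sigma(0) = 0.5: the layer is feature-preserving (up to a
  # constant factor) at initialisation and learns its re-weighting from
  # there, instead of scrambling the fused features before the head has
  # seen them
  conv0 <- conv1d_init(3, 1, 7)
  conv0$W[] <- 0
  list(W_0 = matrix(rnorm(cr * C, 0, sqrt(2 / C)), cr, C),
       b_0 = numeric(cr),
       W_1 = matrix(0, C, cr),
       b_1 = numeric(C),
       conv = conv0,
       C = C, Lp = lp, L = L, r = r)
}

cbam_mlp <- function(v, w) {
  pre <- as.vector(w$W_0 %*% v + w$b_0)
  h <- relu(pre)
  list(out = as.vector(w$W_1 %*% h + w$b_1), pre = pre, h = h, v = v)
}

#' Channel attention gate of CBAM
#'
#' @param f `C x L'` non-negative feature map.
#' @param weights From [cbam_init()].
#' @param mode `"eval"` (deterministic) or `"train"` (sampled stochastic
#'   pooling).
#' @return The gated map `F' = M_c(F) * F` (same shape). The gate vector is
#'   attached as attribute `"M_c"`.
#' @export
channel_attention <- function(f, weights, mode = "eval") {
  r <- channel_attention_fwd(f, weights, train = identical(mode, "train"))
  structure(r$out, M_c = r$mc)
}

channel_attention_fwd <- function(f, w, train = FALSE) {
  if (any(f < -1e-12)) {
    abort("CBAM expects non-negative (post-ReLU) inputs.",
          class = "bcgaf_contract_error")
  }
  avg <- rowMeans(f)
  mx <- apply(f, 1, max)
  sto <- sto_pool_margin(f, 1, train)
  m_avg <- cbam_mlp(avg, w)
  m_max <- cbam_mlp(mx, w)
  m_sto <- cbam_mlp(sto$value, w)
  pre <- m_avg$out + m_max$out + m_sto$out
  mc <- sigmoid(pre)
  list(out = f * mc, mc = mc,
       cache = list(f = f, avg = m_avg, mx = m_max, sto = m_sto,
                    sto_info = sto, pre = pre))
}

channel_attention_bwd <- function(dout, cache, w) {
  f <- cache$f
  mc <- sigmoid(cache$pre)
  dmc <- rowSums(dout * f)
  df <- dout * mc
  dpre <- dmc * mc * (1 - mc)
  grads <- list(W_0 = w$W_0 * 0, b_0 = w$b_0 * 0,
                W_1 = w$W_1 * 0, b_1 = w$b_1 * 0)
  dvecs <- list()
  for (nm in c("avg", "mx", "sto")) {
    ca <- cache[[nm]]
    grads$W_1 <- grads$W_1 + outer(dpre, ca$h)
    grads$b_1 <- grads$b_1 + dpre
    dh <- as.vector(t(w$W_1) %*% dpre)
    dp <- dh * (ca$pre > 0)
    grads$W_0 <- grads$W_0 + outer(dp, ca$v)
    grads$b_0 <- grads$b_0 + dp
    dvecs[[nm]] <- as.vector(t(w$W_0) %*% dp)
  }
  df <- df + dvecs$avg / ncol(f)
  df <- df + row_max_backward(dvecs$mx, f)
  df <- df + sto_pool_margin_backward(dvecs$sto, cache$sto_info, f)
  list(dx = df, grads = grads)
}

#' Spatial attention gate of CBAM
#'
#' @param f_prime `C x L'` map (output of [channel_attention()]).
#' @param weights From [cbam_init()].
#' @param mode `"eval"` or `"train"`.
#' @return The gated map `F'' = M_s(F') * F'` (same shape), with the gate
#'   attached as attribute `"M_s"`.
#' @export
spatial_attention <- function(f_prime, weights, mode = "eval") {
  r <- spatial_attention_fwd(f_prime, weights,
                             train = identical(mode, "train"))
  structure(r$out, M_s = r$ms)
}

spatial_attention_fwd <- function(f, w, train = FALSE) {
  if (ncol(f) < 7) {
    abort("Spatial extent shorter than the length-7 filter.",
          class = "bcgaf_parameter_error")
  }
  avg <- colMeans(f)
  mx <- apply(f, 2, max)
  sto <- sto_pool_margin(f, 2, train)
  p <- cbind(avg = avg, max = mx, sto = sto$value)  # L' x 3 spliced map
  cv <- conv1d_forward(p, w$conv)
  ms <- sigmoid(as.vector(cv$out))
  out <- f * rep(ms, each = nrow(f))
  list(out = out, ms = ms,
       cache = list(f = f, p = p, conv = cv$cache, pre = as.vector(cv$out),
                    sto_info = sto))
}

spatial_attention_bwd <- function(dout, cache, w) {
  f <- cache$f
  ms <- sigmoid(cache$pre)
  dms <- colSums(dout * f)
  df <- dout * rep(ms, each = nrow(f))
  dpre <- dms * ms * (1 - ms)
  cb <- conv1d_backward(matrix(dpre, ncol = 1), cache$conv, w$conv)
  dp <- cb$dx   # L' x 3
  df <- df + matrix(dp[, 1] / nrow(f), nrow(f), ncol(f), byrow = TRUE)
  df <- df + t(row_max_backward(dp[, 2], t(f)))
  df <- df + sto_pool_margin_backward(dp[, 3], cache$sto_info, f)
  list(dx = df, grads = list(conv = cb$grads))
}

cbam_fwd <- function(x, w, train = FALSE) {
  xpad <- c(x, numeric(w$C * w$Lp - length(x)))
  f <- matrix(xpad, w$C, w$Lp)
  ch <- channel_attention_fwd(f, w, train)
  sp <- spatial_attention_fwd(ch$out, w, train)
  list(out = as.vector(sp$out)[seq_len(w$L)],
       cache = list(ch = ch$cache, sp = sp$cache))
}

cbam_bwd <- function(dout, cache, w) {
  df2 <- matrix(c(dout, numeric(w$C * w$Lp - length(dout))), w$C, w$Lp)
  sp <- spatial_attention_bwd(df2, cache$sp, w)
  ch <- channel_attention_bwd(sp$dx, cache$ch, w)
  list(dx = as.vector(ch$dx)[seq_len(w$L)],
       grads = list(W_0 = ch$grads$W_0, b_0 = ch$grads$b_0,
                    W_1 = ch$grads$W_1, b_1 = ch$grads$b_1,
                    conv = sp$grads$conv))
}

#' Apply the full CBAM layer to a fused feature vector
#'
#' Reshapes the vector to `C x L'`, applies the channel gate then the
#' spatial gate, and flattens back to the original length.
#'
#' @param x Numeric non-negative vector of length `weights$L`.
#' @param weights From [cbam_init()].
#' @param mode `"eval"` or `"train"`.
#' @return Vector of the same length as `x`.
#' @export
cbam_layer <- function(x, weights, mode = "eval") {
  cbam_fwd(x, weights, train = identical(mode, "train"))$out
}
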