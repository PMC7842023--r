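# CNN branch for the 2-D rhythm feature.
#
# Twelve listed layers: conv(32, k9) x2, pool(3), conv(64, k9) x2, pool(3),
# conv(128, k9) x2, pool(3), conv(256, k9) x2, pool(3), each pool followed by
# dropout (p = 0.25), then flatten. In sequence mode the rhythm feature is an
# L x 2 series of (v, w) and all kernels are length-9 / pools length-3; in
# image mode the feature is an S x S raster, kernels are 9 x 9 and pools
# (3, 1) reduce only the height (so S = 81 collapses 81 -> 27 -> 9 -> 3 -> 1
# and the flatten width stays S). A standalone dense + softmax head turns the
# branch into the PSR-CNN classifier.

cnn_channels <- c(32, 64, 128, 256)

cnn_flatten_dim <- function(input_len, mode = "sequence", image_size = 81) {
  if (mode == "sequence") {
    l <- input_len
    for (i in 1:4) l <- l %/% 3
    256L * l
  } else {
    h <- image_size
    for (i in 1:4) h <- h %/% 3
    256L * h * image_size
  }
}

cnn_init <- function(mode = c("sequence", "image"), input_len = 2990,
                     image_size = 81, dropout_p = 0.25) {
  mode <- match.arg(mode)
  if (mode == "image" && image_size %% 81 != 0 && image_size %% 3^4 != 0) {
    abort("Image height must be divisible by 3^4 for the four (3, 1) pools.",
          class = "bcgaf_config_error")
  }
  cin <- if (mode == "sequence") 2 else 1
  init <- if (mode == "sequence") conv1d_init else conv2d_init
  layers <- list()
  for (blk in 1:4) {
    cout <- cnn_channels[blk]
    layers[[paste0("conv", 2 * blk - 1)]] <- init(cin, cout, 9)
    layers[[paste0("conv", 2 * blk)]] <- init(cout, cout, 9)
    cin <- cout
  }
  flat <- cnn_flatten_dim(input_len, mode, image_size)
  # classifier heads start at zero so initial logits are uninformative
  # rather than confidently wrong
  layers$head <- dense_init(flat, 2, scale = 0)
  c(layers, list(mode = mode, dropout_p = dropout_p, flat_dim = flat))
}

#' Forward pass of the CNN rhythm branch
#'
#' @param x Rhythm feature: L x 2 matrix (sequence mode) or S x S matrix
#'   (image mode).
#' @param w Branch weights from `cnn_init()`.
#' @param train Logical; activates the four dropout layers.
#' @return List with `flat` (flattened feature vector), `probs`
#'   (standalone-head softmax) and `cache`.
#' @keywords internal
cnn_forward <- function(x, w, train = FALSE) {
  seqm <- w$mode == "sequence"
  if (!seqm && is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1))
  cf <- if (seqm) conv1d_forward else conv2d_forward
  pf <- if (seqm) maxpool1d_forward else maxpool2d_rows_forward
  caches <- list()
  h <- x
  for (blk in 1:4) {
    for (j in 1:2) {
      nm <- paste0("conv", 2 * (blk - 1) + j)
      r <- cf(h, w[[nm]])
      caches[[nm]] <- list(conv = r$cache, pre = r$out)
      h <- relu(r$out)
    }
    r <- pf(h, 3)
    caches[[paste0("pool", blk)]] <- r$cache
    r2 <- dropout_forward(r$out, w$dropout_p, train)
    caches[[paste0("drop", blk)]] <- r2$cache
    h <- r2$out
  }
  flat <- as.vector(h)
  hd <- dense_forward(matrix(flat, 1), w$head)
  list(flat = flat, probs = softmax_rows(hd$out),
       cache = list(layers = caches, shape = dim(h) %||% length(h),
                    head = hd$cache))
}

# dflat: gradient on the flattened vector; dlogits: optional 1 x 2 gradient
# on the standalone head logits.
cnn_backward <- function(dflat, cache, w, dlogits = NULL) {
  grads <- list()
  if (!is.null(dlogits)) {
    hd <- dense_backward(dlogits, cache$head, w$head)
    grads$head <- hd$grads
    dflat <- dflat + as.vector(hd$dx)
  }
  seqm <- w$mode == "sequence"
  cb <- if (seqm) conv1d_backward else conv2d_backward
  pb <- if (seqm) maxpool1d_backward else maxpool2d_rows_backward
  sh <- cache$shape
  dh <- if (length(sh) > 1) array(dflat, dim = sh) else dflat
  if (seqm && is.null(dim(dh))) dh <- matrix(dh, ncol = 256)
  for (blk in 4:1) {
    dh <- dropout_backward(dh, cache$layers[[paste0("drop", blk)]])
    dh <- pb(dh, cache$layers[[paste0("pool", blk)]])
    for (j in 2:1) {
      nm <- paste0("conv", 2 * (blk - 1) + j)
      dh <- relu_backward(dh, cache$layers[[nm]]$pre)
      r <- cb(dh, cache$layers[[nm]]$conv, w[[nm]])
      grads[[nm]] <- r$grads
      dh <- r$dx
    }
  }
  grads
}

# Batched CNN branch over B equal-length sequence features, carried in
# channel-major C x (B*L) layout for contiguous im2col gathers. `feats` is a
# list of L x 2 matrices; the per-sample flatten order matches
# cnn_forward() (position fastest within channel).
cnn_forward_batch <- function(feats, w, train = FALSE) {
  b <- length(feats)
  l <- nrow(feats[[1]])
  x <- t(do.call(rbind, feats))
  caches <- list()
  for (blk in 1:4) {
    for (j in 1:2) {
      nm <- paste0("conv", 2 * (blk - 1) + j)
      r <- conv1d_forward_batch(x, w[[nm]], b, l)
      caches[[nm]] <- list(conv = r$cache, pre = r$out, l = l)
      x <- relu(r$out)
    }
    pr <- maxpool_cm_forward(x, b, l, 3)
    caches[[paste0("pool", blk)]] <- pr$cache
    x <- pr$out
    l <- l %/% 3
    r2 <- dropout_forward(x, w$dropout_p, train)
    caches[[paste0("drop", blk)]] <- r2$cache
    x <- r2$out
  }
  cc <- nrow(x)
  flat <- matrix(0, b, l * cc)
  for (bi in seq_len(b)) {
    flat[bi, ] <- as.vector(t(x[, (bi - 1) * l + seq_len(l), drop = FALSE]))
  }
  list(flat = flat, cache = list(layers = caches, b = b, l_final = l,
                                 c_final = cc))
}

cnn_backward_batch <- function(dflat, cache, w) {
  b <- cache$b
  l <- cache$l_final
  cc <- cache$c_final
  dx <- matrix(0, cc, b * l)
  for (bi in seq_len(b)) {
    dx[, (bi - 1) * l + seq_len(l)] <- t(matrix(dflat[bi, ], l, cc))
  }
  grads <- list()
  for (blk in 4:1) {
    dx <- dropout_backward(dx, cache$layers[[paste0("drop", blk)]])
    dx <- maxpool_cm_backward(dx, cache$layers[[paste0("pool", blk)]])
    for (j in 2:1) {
      nm <- paste0("conv", 2 * (blk - 1) + j)
      ca <- cache$layers[[nm]]
      dx <- relu_backward(dx, ca$pre)
      r <- conv1d_backward_batch(dx, ca$conv, w[[nm]], b, ca$l,
                                 need_dx = nm != "conv1")
      grads[[nm]] <- r$grads
      dx <- r$dx
    }
  }
  grads
}
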