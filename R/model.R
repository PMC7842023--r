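#' Specify an AF-detection network
#'
#' Describes one of the study's classifier configurations: the standalone
#' morphology branch (`"bilstm"`), the standalone rhythm branch
#' (`"psr_cnn"`), or the fused two-branch network (`"ff_cnn"`) whose
#' concatenated flatten vector may pass through a self-attention (`"sam"`)
#' or convolutional-block-attention (`"cbam"`) layer before the classifier
#' head. Defaults follow the study settings: 25 hidden units per LSTM
#' direction (50-wide bidirectional feature), learning rate 5e-4, 30
#' epochs, Adam with batch size 32, dropout 0.5 between the recurrent
#' layers and 0.25 after each pooling layer, SAM scaling constant d = 100,
#' CBAM reshape to 32 channels with reduction 8.
#'
#' @param type `"ff_cnn"`, `"psr_cnn"` or `"bilstm"`.
#' @param attention `"none"`, `"sam"` or `"cbam"` (fused type only).
#' @param mode Rhythm-feature encoding: `"sequence"` (L x 2 series of
#'   `(v, w)`; length-9 kernels) or `"image"` (S x S raster; 9 x 9 kernels,
#'   (3, 1) pools).
#' @param seq_len Rhythm sequence length (3000 - 2 * tau = 2990 at the
#'   default delay).
#' @param image_size Raster side length in image mode.
#' @param hidden_per_dir LSTM hidden units per direction.
#' @param epochs,lr,batch_size Training hyperparameters.
#' @param bilstm_dropout,cnn_dropout Dropout probabilities.
#' @param sam_d SAM softmax scaling constant.
#' @param cbam_channels,cbam_r CBAM reshape channels and reduction ratio.
#' @return A `fusion_model_spec` object.
#' @export
#' @examples
#' fusion_model_spec("ff_cnn", attention = "cbam")
fusion_model_spec <- function(type = c("ff_cnn", "psr_cnn", "bilstm"),
                              attention = c("none", "sam", "cbam"),
                              mode = c("sequence", "image"),
                              seq_len = 2990, image_size = 81,
                              hidden_per_dir = 25,
                              epochs = 30, lr = 5e-4, batch_size = 32,
                              bilstm_dropout = 0.5, cnn_dropout = 0.25,
                              sam_d = 100, cbam_channels = 32, cbam_r = 8) {
  type <- match.arg(type)
  attention <- match.arg(attention)
  mode <- match.arg(mode)
  if (type != "ff_cnn" && attention != "none") {
    abort("Attention layers apply to the fused `ff_cnn` type only.",
          class = "bcgaf_config_error")
  }
  structure(
    list(type = type, attention = attention, mode = mode,
         seq_len = as.integer(seq_len), image_size = as.integer(image_size),
         hidden_per_dir = as.integer(hidden_per_dir),
         epochs = as.integer(epochs), lr = lr,
         batch_size = as.integer(batch_size),
         bilstm_dropout = bilstm_dropout, cnn_dropout = cnn_dropout,
         sam_d = sam_d, cbam_channels = as.integer(cbam_channels),
         cbam_r = as.integer(cbam_r)),
    class = "fusion_model_spec"
  )
}

#' @export
print.fusion_model_spec <- function(x, ...) {
  cat("<fusion_model_spec>", x$type,
      if (x$type == "ff_cnn") paste0("(attention: ", x$attention, ")"), "\n")
  cat("  rhythm mode:", x$mode, "| epochs:", x$epochs, "| lr:", x$lr,
      "| batch:", x$batch_size, "\n")
  invisible(x)
}

fused_length <- function(spec) {
  50L + cnn_flatten_dim(spec$seq_len, spec$mode, spec$image_size)
}

#' Initialise the weights of a model specification
#'
#' @param spec A [fusion_model_spec()].
#' @param seed Integer seed for the draws.
#' @return Nested weight list.
#' @export
init_model_weights <- function(spec, seed = 1) {
  local_seed_eval(derive_seed(seed, "init"), {
    w <- list()
    if (spec$type %in% c("bilstm", "ff_cnn")) {
      w$bilstm <- bilstm_init(1, spec$hidden_per_dir)
    }
    if (spec$type %in% c("psr_cnn", "ff_cnn")) {
      w$cnn <- cnn_init(spec$mode, spec$seq_len, spec$image_size,
                        spec$cnn_dropout)
    }
    if (spec$type == "ff_cnn") {
      lf <- fused_length(spec)
      if (spec$attention == "sam") w$att <- sam_init(lf, spec$sam_d)
      if (spec$attention == "cbam") {
        w$att <- cbam_init(lf, spec$cbam_channels, spec$cbam_r)
      }
      w$head <- dense_init(lf, 2, scale = 0)
    }
    w
  })
}

# Forward pass over a minibatch. x1: B x 125 matrix; feats: list of rhythm
# features. Returns class probabilities (columns: AF, NAF) and, when
# `train`, the caches for the backward pass.
model_forward <- function(w, spec, x1, feats, train = FALSE) {
  if (spec$type == "bilstm") {
    r <- bilstm_forward(x1, w$bilstm, train, spec$bilstm_dropout)
    return(list(probs = r$probs, cache = r$cache))
  }
  if (spec$type == "psr_cnn") {
    if (spec$mode == "sequence") {
      r <- cnn_forward_batch(feats, w$cnn, train)
      hd <- dense_forward(r$flat, w$cnn$head)
      return(list(probs = softmax_rows(hd$out),
                  cache = if (train) list(cnn = r$cache, head = hd$cache)))
    }
    caches <- vector("list", length(feats))
    probs <- matrix(0, length(feats), 2)
    for (b in seq_along(feats)) {
      r <- cnn_forward(feats[[b]], w$cnn, train)
      probs[b, ] <- r$probs
      caches[[b]] <- if (train) r$cache
    }
    return(list(probs = probs, cache = caches))
  }
  # fused
  bl <- bilstm_forward(x1, w$bilstm, train, spec$bilstm_dropout)
  bsz <- nrow(bl$feature)
  if (spec$mode == "sequence") {
    rb <- cnn_forward_batch(feats, w$cnn, train)
    flats <- rb$flat
    cnn_caches <- if (train) rb$cache
  } else {
    flats <- matrix(0, bsz, fused_length(spec) - 50L)
    cnn_caches <- vector("list", bsz)
    for (b in seq_len(bsz)) {
      r <- cnn_forward(feats[[b]], w$cnn, train)
      flats[b, ] <- r$flat
      cnn_caches[[b]] <- if (train) r$cache
    }
  }
  fused_pre <- cbind(bl$feature, flats)
  fused <- relu(fused_pre)   # keeps the stochastic-pooling contract
  att_caches <- vector("list", bsz)
  a <- fused
  if (spec$attention != "none") {
    for (b in seq_len(bsz)) {
      r <- if (spec$attention == "sam") sam_fwd(fused[b, ], w$att)
           else cbam_fwd(fused[b, ], w$att, train)
      a[b, ] <- r$out
      att_caches[[b]] <- if (train) r$cache
    }
  }
  hd <- dense_forward(a, w$head)
  list(probs = softmax_rows(hd$out),
       cache = if (train) list(bl = bl, cnn = cnn_caches,
                               fused_pre = fused_pre, fused = fused,
                               att = att_caches, head = hd$cache))
}

model_backward <- function(dlogits, cache, w, spec) {
  if (spec$type == "bilstm") {
    dfeat <- matrix(0, nrow(dlogits), 50)
    return(list(bilstm = bilstm_backward(dfeat, cache, w$bilstm, dlogits)))
  }
  if (spec$type == "psr_cnn") {
    if (spec$mode == "sequence") {
      hd <- dense_backward(dlogits, cache$head, w$cnn$head)
      g <- cnn_backward_batch(hd$dx, cache$cnn, w$cnn)
      g$head <- hd$grads
      return(list(cnn = g))
    }
    grads <- NULL
    for (b in seq_along(cache)) {
      g <- cnn_backward(numeric(w$cnn$flat_dim), cache[[b]], w$cnn,
                        dlogits[b, , drop = FALSE])
      grads <- tree_add(grads, g)
    }
    return(list(cnn = grads))
  }
  hd <- dense_backward(dlogits, cache$head, w$head)
  da <- hd$dx
  bsz <- nrow(da)
  dfused <- da
  att_grads <- NULL
  if (spec$attention != "none") {
    for (b in seq_len(bsz)) {
      r <- if (spec$attention == "sam") sam_bwd(da[b, ], cache$att[[b]], w$att)
           else cbam_bwd(da[b, ], cache$att[[b]], w$att)
      dfused[b, ] <- r$dx
      att_grads <- tree_add(att_grads, r$grads)
    }
  }
  dfused <- dfused * (cache$fused_pre > 0)
  dbil <- dfused[, 1:50, drop = FALSE]
  if (spec$mode == "sequence") {
    cnn_grads <- cnn_backward_batch(dfused[, -(1:50), drop = FALSE],
                                    cache$cnn, w$cnn)
  } else {
    cnn_grads <- NULL
    for (b in seq_len(bsz)) {
      g <- cnn_backward(dfused[b, -(1:50)], cache$cnn[[b]], w$cnn)
      cnn_grads <- tree_add(cnn_grads, g)
    }
  }
  out <- list(bilstm = bilstm_backward(dbil, cache$bl$cache, w$bilstm),
              cnn = cnn_grads,
              head = hd$grads)
  if (!is.null(att_grads)) out$att <- att_grads
  out
}

#' Prepare network inputs from a segment-pair tibble
#'
#' Computes the phase-space rhythm feature of every 24-s segment at the
#' given `(m, tau)` and stacks the 1-s segments.
#'
#' @param pairs Segment-pair tibble from [preprocess_record()].
#' @param spec A [fusion_model_spec()].
#' @param tau Delay in samples used for the embedding.
#' @return List with `x1` (B x 125 matrix), `feats` (list of rhythm
#'   features), `y` (1 = AF, 2 = NAF), `labels`, `subject_id`,
#'   `segment_id`.
#' @export
prepare_model_inputs <- function(pairs, spec, tau = 5) {
  stopifnot(nrow(pairs) > 0)
  x1 <- do.call(rbind, pairs$seg1)
  feats <- if ("rhythm_feat" %in% names(pairs) &&
               identical(attr(pairs$rhythm_feat[[1]], "mode"), spec$mode)) {
    pairs$rhythm_feat
  } else {
    purrr::map(pairs$seg24, function(s) {
      encode_rhythm_feature(psr_trajectory(s, m = 3, tau = tau),
                            mode = spec$mode, image_size = spec$image_size)
    })
  }
  list(x1 = x1, feats = feats,
       y = ifelse(pairs$label == "AF", 1L, 2L),
       labels = pairs$label, subject_id = pairs$subject_id,
       segment_id = pairs$segment_id)
}

#' Precompute and attach rhythm features to a segment-pair tibble
#'
#' Useful when the same pairs feed several models: the phase-space encoding
#' of every 24-s segment is computed once and stored in a `rhythm_feat`
#' list-column that [prepare_model_inputs()] picks up.
#'
#' @param pairs Segment-pair tibble.
#' @param mode `"sequence"` or `"image"`.
#' @param tau Embedding delay in samples.
#' @param image_size Raster side length for image mode.
#' @return `pairs` with a `rhythm_feat` list-column.
#' @export
precompute_rhythm_features <- function(pairs, mode = "sequence", tau = 5,
                                       image_size = 81) {
  pairs$rhythm_feat <- purrr::map(pairs$seg24, function(s) {
    encode_rhythm_feature(psr_trajectory(s, m = 3, tau = tau),
                          mode = mode, image_size = image_size)
  })
  pairs
}

eval_inputs <- function(w, spec, inputs, idx = seq_along(inputs$y)) {
  probs <- matrix(0, length(idx), 2)
  bs <- 64L
  for (start in seq(1, length(idx), by = bs)) {
    sl <- idx[start:min(start + bs - 1, length(idx))]
    r <- model_forward(w, spec, inputs$x1[sl, , drop = FALSE],
                       inputs$feats[sl], train = FALSE)
    probs[start:(start + length(sl) - 1), ] <- r$probs
  }
  ce <- cross_entropy(probs, inputs$y[idx])
  pred <- ifelse(max.col(probs, ties.method = "first") == 1, "AF", "NAF")
  list(probs = probs, loss = ce$loss,
       acc = mean(pred == inputs$labels[idx]), pred = pred)
}

#' Train an AF-detection model
#'
#' Minimises the cross-entropy with Adam on seeded minibatches. When
#' validation pairs are supplied they must come from different subjects
#' than the training pairs (subject-disjoint contract); the weights with
#' the best validation accuracy are kept.
#'
#' @param spec A [fusion_model_spec()].
#' @param pairs Training segment pairs.
#' @param val_pairs Optional validation segment pairs.
#' @param seed Integer seed driving initialisation, shuffling, dropout and
#'   stochastic pooling.
#' @param tau Embedding delay passed to [prepare_model_inputs()].
#' @param verbose Print per-epoch progress.
#' @return A `bcg_af_model`: list with `spec`, `weights`, `history`
#'   (tibble: epoch, train_loss, train_acc, val_loss, val_acc) and
#'   `best_epoch`.
#' @export
train_model <- function(spec, pairs, val_pairs = NULL, seed = 1, tau = 5,
                        verbose = FALSE) {
  stopifnot(inherits(spec, "fusion_model_spec"))
  if (!is.null(val_pairs) &&
      length(intersect(unique(pairs$subject_id),
                       unique(val_pairs$subject_id))) > 0) {
    abort("Training and validation pairs must be subject-disjoint.",
          class = "bcgaf_split_error")
  }
  tr <- prepare_model_inputs(pairs, spec, tau)
  va <- if (!is.null(val_pairs)) prepare_model_inputs(val_pairs, spec, tau)
  w <- init_model_weights(spec, seed)
  opt <- adam_init(w)
  n <- length(tr$y)
  hist <- vector("list", spec$epochs)
  best <- list(acc = -Inf, w = w, epoch = 0L)
  local_seed_eval(derive_seed(seed, "train"), {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = spec$batch_size)) {
        sl <- ord[start:min(start + spec$batch_size - 1, n)]
        fwd <- model_forward(w, spec, tr$x1[sl, , drop = FALSE],
                             tr$feats[sl], train = TRUE)
        ce <- cross_entropy(fwd$probs, tr$y[sl])
        grads <- model_backward(ce$dlogits, fwd$cache, w, spec)
        st <- adam_step(w, grads, opt, lr = spec$lr)
        w <- st$params
        opt <- st$state
        ep_loss <- ep_loss + ce$loss * length(sl)
        ep_correct <- ep_correct +
          sum(max.col(fwd$probs, ties.method = "first") == tr$y[sl])
      }
      row <- tibble(epoch = ep, train_loss = ep_loss / n,
                    train_acc = ep_correct / n,
                    val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(va)) {
        ev <- eval_inputs(w, spec, va)
        row$val_loss <- ev$loss
        row$val_acc <- ev$acc
        if (ev$acc > best$acc) best <- list(acc = ev$acc, w = w, epoch = ep)
      }
      hist[[ep]] <- row
      if (verbose) {
        cat(sprintf("epoch %2d  train loss %.4f acc %.3f  val acc %s\n",
                    ep, row$train_loss, row$train_acc,
                    ifelse(is.na(row$val_acc), "-",
                           sprintf("%.3f", row$val_acc))))
      }
    }
  })
  final_w <- if (is.null(va)) w else best$w
  structure(list(spec = spec, weights = final_w,
                 history = dplyr::bind_rows(hist),
                 best_epoch = if (is.null(va)) spec$epochs else best$epoch,
                 tau = tau, seed = seed),
            class = "bcg_af_model")
}

#' @export
print.bcg_af_model <- function(x, ...) {
  cat("<bcg_af_model>", x$spec$type,
      if (x$spec$type == "ff_cnn") paste0("+", x$spec$attention), "\n")
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  %d epochs; final train acc %.3f%s\n", nrow(x$history),
              h$train_acc,
              if (!is.na(h$val_acc))
                sprintf("; best val acc %.3f (epoch %d)",
                        max(x$history$val_acc, na.rm = TRUE), x$best_epoch)
              else ""))
  invisible(x)
}

#' Predict AF probabilities for segment pairs
#'
#' @param object A `bcg_af_model`.
#' @param pairs Segment-pair tibble.
#' @param ... Unused.
#' @return Tibble with `segment_id`, `subject_id`, `label`, `prob_af` and
#'   `pred`.
#' @export
predict.bcg_af_model <- function(object, pairs, ...) {
  inputs <- prepare_model_inputs(pairs, object$spec, object$tau)
  ev <- eval_inputs(object$weights, object$spec, inputs)
  tibble(segment_id = inputs$segment_id, subject_id = inputs$subject_id,
         label = inputs$labels, prob_af = ev$probs[, 1], pred = ev$pred)
}
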