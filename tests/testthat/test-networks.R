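# Layer-level behaviour, spec'd shape arithmetic, and exact agreement of the
# hand-written backward passes with central-difference gradients.

test_that("the Bi-LSTM branch emits a 50-wide feature and unit-sum softmax", {
  w <- withr::with_seed(1, bcgaf:::bilstm_init(1, 25))
  X <- withr::with_seed(2, matrix(rnorm(3 * 125), 3, 125))
  r <- bcgaf:::bilstm_forward(X, w, train = FALSE)
  expect_equal(dim(r$feature), c(3, 50))
  expect_equal(rowSums(r$probs), rep(1, 3), tolerance = 1e-6)
})

test_that("zero recurrent weights map any input to a zero feature", {
  w <- bcgaf:::bilstm_init(1, 4)
  w <- rapply(w, function(m) m * 0, how = "replace")
  r <- bcgaf:::bilstm_forward(matrix(rnorm(2 * 20), 2, 20), w, train = FALSE)
  expect_equal(max(abs(r$feature)), 0)
})

test_that("Bi-LSTM backpropagation matches numeric gradients", {
  w <- withr::with_seed(3, bcgaf:::bilstm_init(1, 4))
  X <- withr::with_seed(4, matrix(rnorm(2 * 9), 2, 9))
  R <- withr::with_seed(5, matrix(rnorm(2 * 8), 2, 8))
  y <- c(1L, 2L)
  loss <- function(ww) {
    r <- bcgaf:::bilstm_forward(X, ww, train = FALSE)
    sum(r$feature * R) + bcgaf:::cross_entropy(r$probs, y)$loss
  }
  fw <- bcgaf:::bilstm_forward(X, w, train = FALSE)
  ce <- bcgaf:::cross_entropy(fw$probs, y)
  gr <- bcgaf:::bilstm_backward(R, fw$cache, w, ce$dlogits)
  expect_lt(grad_check(loss, w, gr, n_checks = 3), 1e-5)
})

test_that("CNN flatten dimensions follow the pooling arithmetic", {
  # sequence mode: 2990 -> 996 -> 332 -> 110 -> 36; flatten 256 * 36
  expect_equal(bcgaf:::cnn_flatten_dim(2990, "sequence"), 9216L)
  # image mode: four (3,1) pools collapse the 81 rows; flatten 256 * 1 * 81
  expect_equal(bcgaf:::cnn_flatten_dim(81, "image", 81), 20736L)
  w <- withr::with_seed(6, bcgaf:::cnn_init("sequence", 2990))
  f <- bcgaf:::cnn_forward(matrix(runif(2990 * 2), 2990, 2), w)
  expect_length(f$flat, 9216)
  expect_equal(sum(f$probs), 1, tolerance = 1e-6)
})

test_that("image-mode CNN produces the stated flatten length", {
  w <- withr::with_seed(7, bcgaf:::cnn_init("image", image_size = 81))
  f <- bcgaf:::cnn_forward(matrix(runif(81 * 81), 81, 81), w)
  expect_length(f$flat, 20736)
})

test_that("zero input with zero biases flattens to zero", {
  w <- withr::with_seed(8, bcgaf:::cnn_init("sequence", 243))
  f <- bcgaf:::cnn_forward(matrix(0, 243, 2), w)
  expect_equal(max(abs(f$flat)), 0)
})

test_that("batched and per-sample CNN paths agree exactly", {
  w <- withr::with_seed(9, bcgaf:::cnn_init("sequence", 120, dropout_p = 0))
  feats <- withr::with_seed(10,
    replicate(3, matrix(runif(240), 120, 2), simplify = FALSE))
  fb <- bcgaf:::cnn_forward_batch(feats, w, train = FALSE)
  f1 <- t(sapply(feats, function(f) bcgaf:::cnn_forward(f, w, FALSE)$flat))
  expect_equal(fb$flat, f1, tolerance = 1e-12)
  dflat <- withr::with_seed(11, matrix(rnorm(3 * ncol(fb$flat)), 3))
  gb <- bcgaf:::cnn_backward_batch(dflat, fb$cache, w)
  g1 <- NULL
  for (i in 1:3) {
    ci <- bcgaf:::cnn_forward(feats[[i]], w, TRUE)$cache
    g1 <- bcgaf:::tree_add(g1, bcgaf:::cnn_backward(dflat[i, ], ci, w))
  }
  for (nm in paste0("conv", 1:8)) {
    expect_equal(gb[[nm]]$W, g1[[nm]]$W, tolerance = 1e-10)
    expect_equal(gb[[nm]]$b, g1[[nm]]$b, tolerance = 1e-10)
  }
})

test_that("CNN backpropagation matches numeric gradients", {
  w <- withr::with_seed(12, bcgaf:::cnn_init("sequence", 100, dropout_p = 0))
  x <- withr::with_seed(13, matrix(runif(200), 100, 2))
  R <- withr::with_seed(14, rnorm(w$flat_dim))
  loss <- function(ww) {
    r <- bcgaf:::cnn_forward(x, ww, train = FALSE)
    sum(r$flat * R) + bcgaf:::cross_entropy(r$probs, 1L)$loss
  }
  fw <- bcgaf:::cnn_forward(x, w, train = FALSE)
  ce <- bcgaf:::cross_entropy(fw$probs, 1L)
  gr <- bcgaf:::cnn_backward(R, fw$cache, w, ce$dlogits)
  expect_lt(grad_check(loss, w, gr, n_checks = 2), 1e-5)
})

# SAM ------------------------------------------------------------------------

test_that("SAM chunking geometry follows ceiling(sqrt(L))", {
  w <- withr::with_seed(15, sam_init(125))
  expect_equal(w$T, 12)
  expect_equal(w$n, 11)
  expect_equal(w$n * w$T - 125, 7)   # zero padding
  out <- sam_layer(withr::with_seed(16, runif(125)), w)
  expect_length(out, 125)
})

test_that("zero query/key weights give uniform attention rows", {
  w <- withr::with_seed(17, sam_init(12))
  w$W_Q[] <- 0
  w$W_K[] <- 0
  x <- withr::with_seed(18, runif(12))
  r <- bcgaf:::sam_fwd(x, w)
  expect_equal(r$cache$s, matrix(1 / w$n, w$n, w$n), tolerance = 1e-9)
  # each output row is then the mean of the value rows
  vbar <- colMeans(r$cache$v)
  expect_equal(as.vector(t(r$cache$s %*% r$cache$v)),
               rep(vbar, w$n), tolerance = 1e-9)
  expect_equal(rowSums(r$cache$s), rep(1, w$n), tolerance = 1e-6)
})

test_that("SAM matches a straight-line oracle on a small input", {
  w <- withr::with_seed(19, sam_init(4))
  expect_equal(w$T, 2)
  expect_equal(w$n, 2)
  x <- c(0.3, -0.2, 0.8, 0.1)
  expect_equal(sam_layer(x, w), oracle_sam(x, w), tolerance = 1e-9)
  # larger odd length with padding
  w2 <- withr::with_seed(20, sam_init(11))
  x2 <- withr::with_seed(21, runif(11))
  expect_equal(sam_layer(x2, w2), oracle_sam(x2, w2), tolerance = 1e-9)
  expect_error(sam_layer(c(1, NA, 2, 3), w), class = "bcgaf_numeric_error")
})

test_that("SAM backpropagation matches numeric gradients", {
  w <- withr::with_seed(22, sam_init(11))
  x <- withr::with_seed(23, runif(11))
  dout <- withr::with_seed(24, rnorm(11))
  fw <- bcgaf:::sam_fwd(x, w)
  bw <- bcgaf:::sam_bwd(dout, fw$cache, w)
  loss <- function(sub) {
    w2 <- w
    w2[names(sub)] <- sub
    sum(bcgaf:::sam_fwd(x, w2)$out * dout)
  }
  expect_lt(grad_check(loss, w[c("W_Q", "W_K", "W_V")],
                       bw$grads, n_checks = 4), 1e-6)
})

# Stochastic pooling and CBAM -------------------------------------------------

test_that("stochastic pooling matches its definition in both modes", {
  expect_equal(stochastic_pool(c(1, 3), "eval"), 2.5)
  expect_equal(stochastic_pool(rep(0.7, 5), "eval"), 0.7)
  expect_equal(stochastic_pool(rep(0.7, 5), "train", seed = 1), 0.7)
  expect_equal(stochastic_pool(rep(0, 4), "eval"), 0)
  expect_equal(stochastic_pool(rep(0, 4), "train", seed = 2), 0)
  draw <- stochastic_pool(c(1, 3), "train", seed = 3)
  expect_true(draw %in% c(1, 3))
  expect_identical(draw, stochastic_pool(c(1, 3), "train", seed = 3))
  expect_error(stochastic_pool(c(1, -0.5), "eval"),
               class = "bcgaf_contract_error")
})

test_that("channel attention gates lie in (0,1) and zero input gates at 0.5", {
  w <- withr::with_seed(25, cbam_init(64, C = 8, r = 4))
  f0 <- matrix(0, 8, 8)
  out0 <- channel_attention(f0, w)
  expect_equal(attr(out0, "M_c"), rep(0.5, 8), tolerance = 1e-12)
  expect_equal(max(abs(out0)), 0)
  f <- withr::with_seed(26, matrix(runif(8 * 8), 8, 8))
  out <- channel_attention(f, w)
  expect_true(all(attr(out, "M_c") > 0 & attr(out, "M_c") < 1))
  expect_equal(dim(out), dim(f))
})

test_that("channel attention matches hand-computed gating on a tiny map", {
  w <- withr::with_seed(27, cbam_init(16, C = 2, r = 1))
  w$W_1 <- withr::with_seed(127, matrix(rnorm(4), 2, 2))
  w$b_1 <- c(0.2, -0.1)
  f <- matrix(c(1, 2, 3, 4, 0, 2, 5, 1), 2, 4)
  mlp <- function(v) {
    as.vector(w$W_1 %*% pmax(w$W_0 %*% v + w$b_0, 0) + w$b_1)
  }
  pool_sto <- function(row) sum(row^2) / sum(row)
  mc <- 1 / (1 + exp(-(mlp(rowMeans(f)) +
                         mlp(apply(f, 1, max)) +
                         mlp(apply(f, 1, pool_sto)))))
  expect_equal(unclass(channel_attention(f, w)), f * mc,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("spatial attention preserves shape and matches a brute-force oracle", {
  w <- withr::with_seed(28, cbam_init(16, C = 2, r = 1))
  w$conv$W <- withr::with_seed(128, array(rnorm(21, 0, 0.5), dim = c(3, 1, 7)))
  w$conv$b <- 0.1
  f <- withr::with_seed(29, matrix(runif(2 * 8), 2, 8))
  out <- spatial_attention(f, w)
  expect_equal(dim(out), dim(f))
  expect_true(all(attr(out, "M_s") > 0 & attr(out, "M_s") < 1))
  # straight-line oracle: splice pools, length-7 'same' convolution, sigmoid
  pools <- rbind(colMeans(f), apply(f, 2, max),
                 apply(f, 2, function(col) sum(col^2) / sum(col)))
  ms <- numeric(8)
  kern <- w$conv$W   # dims (3, 1, 7)
  for (pos in 1:8) {
    acc <- w$conv$b
    for (ki in 1:7) {
      src <- pos + ki - 4
      if (src >= 1 && src <= 8) acc <- acc + sum(kern[, 1, ki] * pools[, src])
    }
    ms[pos] <- 1 / (1 + exp(-acc))
  }
  expect_equal(unclass(out), f * rep(ms, each = 2),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(attr(out, "M_s"), ms, tolerance = 1e-9)
})

test_that("the full CBAM layer preserves length and zeroes with zero input", {
  w <- withr::with_seed(30, cbam_init(60, C = 8, r = 4))
  expect_equal(cbam_layer(rep(0, 60), w), rep(0, 60))
  x <- withr::with_seed(31, runif(60))
  expect_length(cbam_layer(x, w), 60)
  expect_error(cbam_init(60, C = 8, r = 8), class = "bcgaf_parameter_error")
})

test_that("CBAM backpropagation matches numeric gradients in eval mode", {
  w <- withr::with_seed(32, cbam_init(60, C = 8, r = 4))
  x <- withr::with_seed(33, runif(60))
  dout <- withr::with_seed(34, rnorm(60))
  fw <- bcgaf:::cbam_fwd(x, w, train = FALSE)
  bw <- bcgaf:::cbam_bwd(dout, fw$cache, w)
  loss <- function(sub) {
    w2 <- w
    w2[names(sub)] <- sub
    sum(bcgaf:::cbam_fwd(x, w2, train = FALSE)$out * dout)
  }
  expect_lt(grad_check(loss, w[c("W_0", "b_0", "W_1", "b_1", "conv")],
                       bw$grads, n_checks = 3), 1e-5)
})

# Fused model -----------------------------------------------------------------

test_that("without attention the fused head consumes the plain concatenation", {
  spec <- fusion_model_spec("ff_cnn", attention = "none", seq_len = 100,
                            bilstm_dropout = 0, cnn_dropout = 0)
  w <- init_model_weights(spec, 41)
  x1 <- withr::with_seed(42, matrix(rnorm(125), 1, 125))
  feats <- list(withr::with_seed(43, matrix(runif(200), 100, 2)))
  r <- bcgaf:::model_forward(w, spec, x1, feats, train = FALSE)
  # manual recomputation: branch features -> relu -> dense -> softmax
  bl <- bcgaf:::bilstm_forward(x1, w$bilstm, FALSE)
  cn <- bcgaf:::cnn_forward(feats[[1]], w$cnn, FALSE)
  fused <- pmax(cbind(bl$feature, matrix(cn$flat, 1)), 0)
  logits <- fused %*% w$head$W + w$head$b
  expect_equal(as.vector(r$probs),
               as.vector(exp(logits) / sum(exp(logits))), tolerance = 1e-9)
  expect_equal(sum(r$probs), 1, tolerance = 1e-6)
})

test_that("fused forward passes are deterministic in eval mode", {
  for (att in c("sam", "cbam")) {
    spec <- fusion_model_spec("ff_cnn", attention = att, seq_len = 100)
    w <- init_model_weights(spec, 44)
    x1 <- withr::with_seed(45, matrix(rnorm(2 * 125), 2, 125))
    feats <- withr::with_seed(46, replicate(2, matrix(runif(200), 100, 2),
                                            simplify = FALSE))
    a <- bcgaf:::model_forward(w, spec, x1, feats, train = FALSE)$probs
    b <- bcgaf:::model_forward(w, spec, x1, feats, train = FALSE)$probs
    expect_identical(a, b)
    expect_equal(rowSums(a), c(1, 1), tolerance = 1e-6)
  }
})

test_that("training runs, is seed-reproducible, and rejects subject overlap", {
  pairs <- fixture_pairs()
  tiny <- pairs[pairs$subject_id %in% c("S01", "S02"), ][1:8, ]
  spec <- fusion_model_spec("ff_cnn", attention = "cbam", epochs = 1,
                            batch_size = 4)
  fit <- train_model(spec, tiny, seed = 50)
  expect_true(is.finite(fit$history$train_loss[1]))
  fit2 <- train_model(spec, tiny, seed = 50)
  expect_identical(fit$weights, fit2$weights)
  expect_error(train_model(spec, tiny, val_pairs = tiny, seed = 50),
               class = "bcgaf_split_error")
})

test_that("a linearly separable toy fusion task is learnt to 100% accuracy", {
  # two Gaussian classes in both branch inputs; sequence-mode CNN at a
  # small length keeps each epoch cheap
  set.seed(51)
  n <- 16
  mk_pairs <- function() {
    tibble::tibble(
      segment_id = sprintf("T%02d", 1:n),
      subject_id = rep(c("A", "B"), each = n / 2),
      label = rep(c("AF", "NAF"), n / 2),
      seg24 = lapply(1:n, function(i) {
        mu <- if (i %% 2 == 1) 0.3 else 0.7
        pmin(pmax(rnorm(300, mu, 0.05), 0), 1)
      }),
      seg1 = lapply(1:n, function(i) {
        mu <- if (i %% 2 == 1) 0.2 else 0.8
        pmin(pmax(rnorm(125, mu, 0.05), 0), 1)
      }),
      j_index = 63L
    )
  }
  pairs <- mk_pairs()
  spec <- fusion_model_spec("ff_cnn", attention = "none", seq_len = 290,
                            epochs = 50, lr = 2e-3, batch_size = 8,
                            bilstm_dropout = 0, cnn_dropout = 0)
  fit <- train_model(spec, pairs, seed = 52)
  expect_equal(max(fit$history$train_acc), 1)
  expect_lte(which.max(fit$history$train_acc == 1), 50)
})

test_that("2-D convolution and row pooling match numeric gradients", {
  p <- withr::with_seed(60, bcgaf:::conv2d_init(2, 3, 9))
  x <- withr::with_seed(61, array(runif(9 * 9 * 2), dim = c(9, 9, 2)))
  dout <- withr::with_seed(62, array(rnorm(9 * 9 * 3), dim = c(9, 9, 3)))
  fw <- bcgaf:::conv2d_forward(x, p)
  bw <- bcgaf:::conv2d_backward(dout, fw$cache, p)
  loss <- function(sub) {
    p2 <- p
    p2[names(sub)] <- sub
    sum(bcgaf:::conv2d_forward(x, p2)$out * dout)
  }
  expect_lt(grad_check(loss, p[c("W", "b")], bw$grads, n_checks = 4), 1e-6)
  # input gradient
  idx <- sample(length(x), 6)
  xe <- vapply(idx, function(i) {
    numeric_grad(function(v) {
      x2 <- x
      x2[i] <- v
      sum(bcgaf:::conv2d_forward(x2, p)$out * dout)
    }, x[i])
  }, numeric(1))
  expect_equal(bw$dx[idx], xe, tolerance = 1e-6)

  # (3, 1) pooling: forward picks column-wise maxima of each 3-row band and
  # backward routes gradients to exactly those positions
  xp <- withr::with_seed(63, array(runif(9 * 4 * 2), dim = c(9, 4, 2)))
  pf <- bcgaf:::maxpool2d_rows_forward(xp, 3)
  expect_equal(dim(pf$out), c(3, 4, 2))
  for (j in 1:4) {
    for (c2 in 1:2) {
      expect_equal(pf$out[, j, c2],
                   c(max(xp[1:3, j, c2]), max(xp[4:6, j, c2]),
                     max(xp[7:9, j, c2])))
    }
  }
  dpo <- withr::with_seed(64, array(rnorm(3 * 4 * 2), dim = c(3, 4, 2)))
  dxp <- bcgaf:::maxpool2d_rows_backward(dpo, pf$cache)
  expect_equal(sum(dxp != 0), 3 * 4 * 2)
  expect_equal(sum(dxp), sum(dpo))
})
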