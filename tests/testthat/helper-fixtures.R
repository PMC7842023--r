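# Shared fixtures and independent oracles, built in code at test time.

# One small default-noise cohort reused across tests (computed lazily once).
fixture_env <- new.env(parent = emptyenv())

fixture_pairs <- function() {
  if (is.null(fixture_env$pairs)) {
    co <- generate_cohort(4, 8, seed = 301)
    fixture_env$cohort <- co
    fixture_env$pairs <- preprocess_cohort(co)
  }
  fixture_env$pairs
}

fixture_cohort <- function() {
  invisible(fixture_pairs())
  fixture_env$cohort
}

# A clean (noise-free, jitter-free) preprocessed NAF segment.
clean_naf_segment <- function(seed = 401, n_beats = 45) {
  rec <- render_bcg(generate_rr_series(rhythm_spec("NAF"), n_beats, seed),
                    fs = 125, noise_sd = 0, drift_amp = 0.1,
                    amp_jitter_cv = 0, seed = seed)
  x <- normalize_signal(bandpass_filter(rec$samples, 125))
  x[seq_len(3000)]
}

# Independent brute-force false-nearest-neighbour oracle: plain double loop
# over points, no shared code with fnn_fraction().
oracle_fnn_fraction <- function(x, m, tau, rtol = 15, atol = 2,
                                theiler = tau) {
  n_pts <- length(x) - m * tau
  r_a <- sd(x)
  n_false <- 0
  for (i in seq_len(n_pts)) {
    pi_ <- x[i + (0:(m - 1)) * tau]
    best <- Inf
    nn <- NA_integer_
    for (j in seq_len(n_pts)) {
      if (abs(i - j) <= theiler) next
      d <- sqrt(sum((pi_ - x[j + (0:(m - 1)) * tau])^2))
      if (d < best) {
        best <- d
        nn <- j
      }
    }
    dd <- abs(x[i + m * tau] - x[nn + m * tau])
    if (dd > rtol * max(best, 1e-10 * r_a) ||
        sqrt(best^2 + dd^2) / r_a > atol) {
      n_false <- n_false + 1
    }
  }
  n_false / n_pts
}

# Straight-line evaluation of the chunked self-attention layer, written
# independently of sam_layer().
oracle_sam <- function(x, w) {
  tt <- w$T
  n <- w$n
  xp <- c(x, rep(0, n * tt - length(x)))
  rows <- matrix(xp, n, tt, byrow = TRUE)
  q <- pmax(rows %*% w$W_Q, 0)
  k <- pmax(rows %*% w$W_K, 0)
  v <- pmax(rows %*% w$W_V, 0)
  logits <- q %*% t(k) / sqrt(w$d)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) s[i, ] <- exp(logits[i, ]) / sum(exp(logits[i, ]))
  a <- s %*% v
  out <- numeric(n * tt)
  for (i in seq_len(n)) out[(i - 1) * tt + seq_len(tt)] <- a[i, ]
  out[seq_len(length(x))]
}

# Central-difference helper for gradient checks.
numeric_grad <- function(f, x, eps = 1e-5) {
  (f(x + eps) - f(x - eps)) / (2 * eps)
}

# Relative error between an analytic gradient tree and central differences,
# sampling a few entries per parameter tensor.
grad_check <- function(loss_fn, params, grads, n_checks = 2) {
  assign_leaf <- function(tree, path, val) {
    if (length(path) == 0) return(val)
    tree[[path[1]]] <- assign_leaf(tree[[path[1]]], path[-1], val)
    tree
  }
  worst <- 0
  walk <- function(p, g, path) {
    if (is.numeric(p) && !is.null(g)) {
      for (i in sample(length(p), min(n_checks, length(p)))) {
        f <- function(v) {
          p2 <- p
          p2[i] <- v
          loss_fn(assign_leaf(params, path, p2))
        }
        ng <- numeric_grad(f, p[i])
        worst <<- max(worst, abs(ng - g[i]) / max(1e-6, abs(ng) + abs(g[i])))
      }
    } else if (is.list(p)) {
      for (nm in names(p)) walk(p[[nm]], g[[nm]], c(path, nm))
    }
  }
  walk(params, grads, character(0))
  worst
}
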