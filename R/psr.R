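#' Time-delay selection by the autocorrelation first zero crossing
#'
#' Computes the unbiased normalised autocorrelation and returns the smallest
#' lag at which it first changes sign. If no crossing occurs within
#' `max_lag_s`, the maximum lag is returned with a warning.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param max_lag_s Largest lag searched, in seconds.
#' @return Integer lag in samples (>= 1).
#' @export
#' @examples
#' autocorr_delay(cos(2 * pi * (0:999) / 40), fs = 125) # quarter period = 10
autocorr_delay <- function(x, fs, max_lag_s = 2) {
  check_numeric_vector(x)
  max_lag <- round(max_lag_s * fs)
  if (length(x) <= 2 * max_lag) {
    abort("Signal too short for the requested maximum lag.",
          class = "bcgaf_input_error")
  }
  if (var(x) <= .Machine$double.eps) {
    abort("Constant signal has no autocorrelation structure.",
          class = "bcgaf_degenerate_input")
  }
  r <- autocorr_unbiased(x, max_lag)
  prev <- 1
  for (k in seq_len(max_lag)) {
    if (sign(r[k]) != sign(prev) || r[k] == 0) return(k)
    prev <- r[k]
  }
  warn("No autocorrelation zero crossing within `max_lag_s`; returning the maximum lag.",
       class = "bcgaf_no_crossing")
  max_lag
}

# Unbiased normalised autocorrelation for lags 1..max_lag.
autocorr_unbiased <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  v <- sum(xc^2) / n
  vapply(seq_len(max_lag), function(k) {
    sum(xc[1:(n - k)] * xc[(k + 1):n]) / (n - k) / v
  }, numeric(1))
}

#' Embedding dimension by false nearest neighbours
#'
#' For each trial dimension `m`, embeds the signal with delay `tau`, finds
#' every point's Euclidean nearest neighbour (excluding temporal neighbours
#' within `theiler` samples), and marks the pair false when either the
#' relative distance increase on adding the `(m+1)`-th coordinate exceeds
#' `rtol`, or the new distance exceeds `atol` times the attractor size
#' (the signal SD). The smallest `m` whose false fraction falls below
#' `fnn_threshold` is returned; if none qualifies, `m_max` with a warning.
#'
#' @param x Numeric signal, length at least `50 * m_max`.
#' @param tau Delay in samples.
#' @param m_max Largest dimension tried.
#' @param rtol Relative distance-increase threshold (classic default 15).
#' @param atol Attractor-size threshold (classic default 2).
#' @param fnn_threshold False-neighbour fraction below which `m` is accepted.
#' @param theiler Temporal exclusion window in samples; defaults to `tau`.
#' @return Integer embedding dimension.
#' @export
fnn_embedding_dim <- function(x, tau, m_max = 10, rtol = 15, atol = 2,
                              fnn_threshold = 0.01, theiler = tau) {
  check_numeric_vector(x)
  check_scalar(tau, "tau", lower = 1)
  if (length(x) < 50 * m_max) {
    abort("Signal too short for FNN estimation at this `m_max`.",
          class = "bcgaf_input_error")
  }
  for (m in seq_len(m_max)) {
    frac <- fnn_fraction(x, m, tau, rtol, atol, theiler)
    if (is.finite(frac) && frac < fnn_threshold) return(m)
  }
  warn("No dimension reached the FNN threshold; returning `m_max`.",
       class = "bcgaf_fnn_saturated")
  m_max
}

#' False-neighbour fraction at one dimension
#'
#' @inheritParams fnn_embedding_dim
#' @param m Trial embedding dimension.
#' @return Fraction of points whose nearest neighbour in dimension `m`
#'   becomes false in dimension `m + 1`.
#' @export
fnn_fraction <- function(x, m, tau, rtol = 15, atol = 2, theiler = tau) {
  n_pts <- length(x) - m * tau   # need the (m+1)-th coordinate as well
  if (n_pts < 10) return(NA_real_)
  emb <- vapply(0:(m - 1), function(j) x[seq_len(n_pts) + j * tau],
                numeric(n_pts))
  if (!is.matrix(emb)) emb <- matrix(emb, ncol = m)
  d2 <- as.matrix(stats::dist(emb))^2
  # exclude self and temporal neighbours within the Theiler window
  for (k in 0:theiler) {
    i <- seq_len(n_pts - k)
    d2[cbind(i, i + k)] <- Inf
    d2[cbind(i + k, i)] <- Inf
  }
  nn <- max.col(-d2, ties.method = "first")
  r_m <- sqrt(d2[cbind(seq_len(n_pts), nn)])
  extra <- x[seq_len(n_pts) + m * tau]
  dd <- abs(extra - extra[nn])
  r_a <- sd(x)
  floor_eps <- 1e-10 * r_a
  false1 <- dd > rtol * pmax(r_m, floor_eps)
  false2 <- sqrt(r_m^2 + dd^2) / r_a > atol
  mean(false1 | false2)
}

#' Takens delay embedding
#'
#' Row `i` of the result is `(x[i], x[i - tau], ..., x[i - (m-1) tau])` for
#' `i` running over the admissible range, so for `m = 3` the columns are the
#' current sample and its `tau`- and `2 tau`-delayed copies.
#'
#' @param x Numeric signal.
#' @param m Embedding dimension (>= 2).
#' @param tau Delay in samples (>= 1).
#' @return Numeric matrix with `length(x) - (m - 1) * tau` rows and `m`
#'   columns.
#' @export
#' @examples
#' delay_embed(0:9, m = 3, tau = 2)[1, ] # 4 2 0
delay_embed <- function(x, m = 3, tau) {
  check_numeric_vector(x)
  check_scalar(m, "m", lower = 2)
  check_scalar(tau, "tau", lower = 1)
  n <- length(x)
  span <- (m - 1) * tau
  if (n <= span) {
    abort("Signal shorter than the embedding span (m - 1) * tau.",
          class = "bcgaf_parameter_error")
  }
  idx <- (span + 1):n
  out <- vapply(0:(m - 1), function(j) x[idx - j * tau],
                numeric(length(idx)))
  dimnames(out) <- NULL
  out
}

#' Project delay coordinates onto the plane orthogonal to (1, 1, 1)
#'
#' Orthonormal rotation `u = (x + y + z)/sqrt(3)`, `v = (x + y - 2 z)/sqrt(6)`,
#' `w = (x - y)/sqrt(2)`; `u` carries the baseline (any constant shift of the
#' signal moves points only along `u`), so the `(v, w)` plane is invariant to
#' baseline translation and is kept as the 2-D rhythm portrait.
#'
#' @param xyz N x 3 matrix of delay coordinates.
#' @return List with `uvw` (N x 3) and `vw` (N x 2).
#' @export
project_uvw <- function(xyz) {
  if (!is.matrix(xyz) || ncol(xyz) != 3 || nrow(xyz) == 0) {
    abort("`xyz` must be a non-empty N x 3 matrix.",
          class = "bcgaf_input_error")
  }
  u <- (xyz[, 1] + xyz[, 2] + xyz[, 3]) / sqrt(3)
  v <- (xyz[, 1] + xyz[, 2] - 2 * xyz[, 3]) / sqrt(6)
  w <- (xyz[, 1] - xyz[, 2]) / sqrt(2)
  list(uvw = cbind(u = u, v = v, w = w), vw = cbind(v = v, w = w))
}

#' Phase-space trajectory of one 24-s segment
#'
#' Convenience wrapper: delay-embeds the segment and projects it. The
#' projection is defined for `m = 3` only; requesting another dimension is
#' an error rather than a silent reinterpretation.
#'
#' @param x Normalised segment samples.
#' @param m Embedding dimension; must be 3.
#' @param tau Delay in samples.
#' @return A `psr_trajectory`: list with `xyz`, `uvw`, `vw`, `m`, `tau`.
#' @export
psr_trajectory <- function(x, m = 3, tau = 5) {
  if (m != 3) {
    abort("The (u, v, w) projection is defined for m = 3 only.",
          class = "bcgaf_parameter_error")
  }
  xyz <- delay_embed(x, m = 3, tau = tau)
  pr <- project_uvw(xyz)
  structure(list(xyz = xyz, uvw = pr$uvw, vw = pr$vw, m = m, tau = tau),
            class = "psr_trajectory")
}

#' @export
print.psr_trajectory <- function(x, ...) {
  cat("<psr_trajectory>", nrow(x$xyz), "points, m =", x$m, ", tau =", x$tau,
      "samples\n")
  invisible(x)
}

#' Encode a projected trajectory as the CNN rhythm feature
#'
#' Image mode rasterises the `(v, w)` points into a fixed-bounds 2-D
#' histogram (`v` in `[-2/sqrt(6), 2/sqrt(6)]`, `w` in
#' `[-1/sqrt(2), 1/sqrt(2)]`, the exact attainable range for unit-normalised
#' signals), then applies `log1p` and max-normalisation to `[0, 1]`; fixed
#' bounds keep pixel geometry comparable across segments. Sequence mode
#' passes the `(v, w)` coordinate series through unchanged.
#'
#' @param vw N x 2 matrix of projected points (or a `psr_trajectory`).
#' @param mode `"sequence"` or `"image"`.
#' @param image_size Image side length in pixels.
#' @return For `"image"`, an `image_size` x `image_size` matrix in `[0, 1]`
#'   with attribute `mode`; for `"sequence"`, the N x 2 matrix with
#'   attribute `mode`.
#' @export
encode_rhythm_feature <- function(vw, mode = c("sequence", "image"),
                                  image_size = 81) {
  if (inherits(vw, "psr_trajectory")) vw <- vw$vw
  mode <- match.arg(mode)
  if (!is.matrix(vw) || ncol(vw) != 2 || nrow(vw) == 0) {
    abort("`vw` must be a non-empty N x 2 matrix.", class = "bcgaf_input_error")
  }
  if (mode == "sequence") {
    return(structure(vw, mode = "sequence"))
  }
  vb <- c(-2 / sqrt(6), 2 / sqrt(6))
  wb <- c(-1 / sqrt(2), 1 / sqrt(2))
  iv <- bin_index(vw[, 1], vb, image_size)
  iw <- bin_index(vw[, 2], wb, image_size)
  counts <- matrix(0, image_size, image_size)
  tab <- table(factor(iv, levels = seq_len(image_size)),
               factor(iw, levels = seq_len(image_size)))
  counts[] <- as.numeric(tab)
  img <- log1p(counts)
  mx <- max(img)
  if (mx > 0) img <- img / mx
  structure(img, mode = "image")
}

bin_index <- function(x, bounds, n_bins) {
  i <- floor((x - bounds[1]) / (bounds[2] - bounds[1]) * n_bins) + 1
  pmin(pmax(i, 1), n_bins)
}

#' Trajectory dispersion: mean distance to the centroid
#'
#' A scalar summary of how spread-out the 2-D portrait is; irregular (AF)
#' rhythm smears the trajectory, so AF segments score higher than NAF.
#'
#' @param vw N x 2 matrix or `psr_trajectory`.
#' @return Mean Euclidean distance of the points to their centroid.
#' @export
trajectory_dispersion <- function(vw) {
  if (inherits(vw, "psr_trajectory")) vw <- vw$vw
  ctr <- colMeans(vw)
  mean(sqrt((vw[, 1] - ctr[1])^2 + (vw[, 2] - ctr[2])^2))
}

#' Estimate (m, tau) for a segment, or take the study defaults
#'
#' @param x Segment samples.
#' @param fs Sampling rate in Hz.
#' @param tau `"auto"` to estimate via [autocorr_delay()], or an integer lag.
#' @param m `"auto"` to estimate via [fnn_embedding_dim()], or an integer.
#' @param max_lag_s,m_max Passed to the estimators.
#' @return List with integer `m` and `tau`.
#' @export
embedding_params <- function(x, fs = 125, tau = "auto", m = "auto",
                             max_lag_s = 2, m_max = 10) {
  tau_v <- if (identical(tau, "auto")) autocorr_delay(x, fs, max_lag_s)
           else as.integer(tau)
  m_v <- if (identical(m, "auto")) fnn_embedding_dim(x, tau_v, m_max = m_max)
         else as.integer(m)
  list(m = m_v, tau = tau_v)
}
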