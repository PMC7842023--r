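#' Zero-phase Butterworth bandpass filter
#'
#' Applies an order-`order` Butterworth bandpass (default 0.7-10 Hz, the band
#' retaining the heartbeat complex while rejecting respiration and baseline
#' drift) forward and backward, so the net response is zero-phase and J-peak
#' latencies are not shifted.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Filter order of each pass.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 0.7, high = 10, order = 4) {
  check_numeric_vector(x)
  check_scalar(fs, "fs", lower = 1e-9)
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort("Band edges must satisfy 0 < low < high < fs/2.",
          class = "bcgaf_parameter_error")
  }
  if (length(x) < 3 * order) {
    abort("Signal too short for the requested filter order.",
          class = "bcgaf_degenerate_input")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # odd-reflection padding lets the zero-initial-state forward-backward
  # passes settle outside the record, so edge transients are trimmed away
  n <- length(x)
  pad <- min(n - 1, round(10 * fs / low))
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(front, x, back)))
  y[(pad + 1):(pad + n)]
}

#' Detect motion / out-of-bed artifacts from the signal envelope
#'
#' Splits the record into `win_s`-second windows, computes the RMS envelope
#' per window, and flags windows whose envelope exceeds `k_hi` times or falls
#' below `k_lo` times the median window envelope. Adjacent flagged windows
#' are merged into intervals.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param win_s Envelope window length in seconds.
#' @param k_hi,k_lo Multiplicative thresholds on the median envelope.
#' @return Tibble with columns `start_s`, `end_s`; zero rows for a clean
#'   record. A warning is raised when the whole record is flagged.
#' @export
detect_artifacts <- function(x, fs, win_s = 2, k_hi = 3, k_lo = 0.2) {
  check_numeric_vector(x)
  w <- round(win_s * fs)
  if (length(x) < w) {
    abort("Signal shorter than one envelope window.",
          class = "bcgaf_degenerate_input")
  }
  n_win <- length(x) %/% w
  rms <- vapply(seq_len(n_win), function(i) {
    seg <- x[((i - 1) * w + 1):(i * w)]
    sqrt(mean(seg^2))
  }, numeric(1))
  med <- median(rms)
  flagged <- if (med <= .Machine$double.eps) {
    rep(TRUE, n_win)
  } else {
    rms > k_hi * med | rms < k_lo * med
  }
  if (all(flagged)) {
    warn("Entire record flagged as artifact; no usable signal remains.",
         class = "bcgaf_all_flagged")
  }
  mask_from_flags(flagged, w, fs)
}

mask_from_flags <- function(flagged, w, fs) {
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble(start_s = (starts[keep] - 1) * w / fs,
         end_s = ends[keep] * w / fs)
}

in_mask <- function(start_s, end_s, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(FALSE)
  any(mask$start_s < end_s & mask$end_s > start_s)
}

#' Min-max normalisation to the unit interval
#'
#' Affinely maps the signal so that the minimum over unmasked samples
#' becomes 0 and the maximum becomes 1, suppressing inter-subject amplitude
#' differences before feature extraction.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz (needed only when `mask` is given).
#' @param mask Optional artifact mask tibble; masked samples are excluded
#'   from the min/max but still mapped.
#' @return Normalised signal.
#' @export
normalize_signal <- function(x, fs = NULL, mask = NULL) {
  check_numeric_vector(x)
  use <- rep(TRUE, length(x))
  if (!is.null(mask) && nrow(mask) > 0) {
    stopifnot(!is.null(fs))
    for (i in seq_len(nrow(mask))) {
      i0 <- max(1L, floor(mask$start_s[i] * fs) + 1L)
      i1 <- min(length(x), ceiling(mask$end_s[i] * fs))
      use[i0:i1] <- FALSE
    }
    if (!any(use)) use <- rep(TRUE, length(x))
  }
  lo <- min(x[use])
  hi <- max(x[use])
  if (hi - lo <= .Machine$double.eps) {
    abort("Constant signal cannot be min-max normalised.",
          class = "bcgaf_degenerate_input")
  }
  (x - lo) / (hi - lo)
}

#' Detect J-peaks in a normalised, bandpassed BCG signal
#'
#' The J wave is the dominant positive deflection of the heartbeat complex,
#' so peak picking suffices: a sample qualifies when it is the maximum of its
#' `+/- peak_win_s` neighbourhood, rises by at least `prominence` (in
#' normalised units) above the higher of the surrounding troughs, and lies at
#' least `min_rr_s` from any larger retained peak (larger peaks win ties).
#'
#' @param x Normalised signal in `[0, 1]`.
#' @param fs Sampling rate in Hz.
#' @param min_rr_s Minimum inter-peak distance in seconds.
#' @param prominence Minimum peak prominence in normalised units.
#' @param peak_win_s Local-maximum window half-width in seconds.
#' @return Strictly increasing integer vector of peak sample indices
#'   (1-based), possibly empty.
#' @export
detect_j_peaks <- function(x, fs, min_rr_s = 0.4, prominence = 0.15,
                           peak_win_s = 0.15) {
  check_numeric_vector(x)
  n <- length(x)
  w <- max(1L, round(peak_win_s * fs))
  rmax <- running_max(x, w)
  cand <- which(x >= rmax - 1e-12)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] > x[cand - 1] & x[cand] >= x[cand + 1]]
  if (length(cand) == 0) return(integer(0))

  # simplified prominence: drop to the lowest point within +/- trough_w
  trough_w <- max(1L, round(0.3 * fs))
  prom <- vapply(cand, function(i) {
    left <- min(x[max(1L, i - trough_w):i])
    right <- min(x[i:min(n, i + trough_w)])
    x[i] - max(left, right)
  }, numeric(1))
  cand <- cand[prom >= prominence]
  if (length(cand) == 0) return(integer(0))

  # enforce the refractory distance, larger peaks first
  min_dist <- round(min_rr_s * fs)
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 || all(abs(kept - i) >= min_dist)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

running_max <- function(x, w) {
  r <- x
  for (k in seq_len(w)) {
    n <- length(x)
    r <- pmax(r,
              c(x[-seq_len(k)], rep(-Inf, k)),
              c(rep(-Inf, k), x[seq_len(n - k)]))
  }
  r
}

#' Cut a labelled record into paired 24-s and 1-s segments
#'
#' Walks each label interval in non-overlapping 24-s steps, discards windows
#' touching the artifact mask, and pairs every retained 24-s rhythm segment
#' with one 1-s morphology segment centred on a J-peak: the detected peak
#' nearest the window centre that keeps a full 0.5-s margin inside the
#' window (62 samples before the peak, 62 after; the peak sits at index 63
#' of 125, i.e. 0-based index 62). Windows without such a peak are dropped,
#' and label intervals shorter than 24 s are skipped with a notice.
#'
#' @param record A `bcg_record` (labels are taken from it).
#' @param x Preprocessed (filtered + normalised) samples of the record.
#' @param peaks J-peak indices from [detect_j_peaks()].
#' @param mask Artifact mask tibble (possibly empty).
#' @return Tibble with one row per pair: `segment_id`, `subject_id`,
#'   `label`, `start_s`, `seg24` (list, 3000 samples), `seg1` (list, 125
#'   samples), `j_index` (1-based index of J within `seg1`, always 63) and
#'   `peaks` (list of within-window peak indices, window-relative).
#' @export
segment_record <- function(record, x, peaks, mask = NULL) {
  stopifnot(inherits(record, "bcg_record"))
  fs <- record$fs
  len24 <- 24 * fs
  half1 <- 62L          # samples kept before the J-peak of the 1-s segment
  len1 <- 125L
  rows <- list()
  k <- 0
  for (li in seq_len(nrow(record$label_intervals))) {
    iv <- record$label_intervals[li, ]
    if (iv$end_s - iv$start_s < 24) {
      inform(sprintf("Label interval %.1f-%.1f s shorter than 24 s; skipped.",
                     iv$start_s, iv$end_s))
      next
    }
    n_win <- floor((iv$end_s - iv$start_s) / 24)
    for (wi in seq_len(n_win)) {
      a <- round(iv$start_s * fs) + (wi - 1) * len24 + 1L
      b <- a + len24 - 1L
      if (b > length(x)) next
      if (in_mask((a - 1) / fs, b / fs, mask)) next
      pk <- peaks[peaks >= a & peaks <= b]
      ok <- pk[pk - half1 >= a & pk + half1 <= b]
      if (length(ok) == 0) next
      centre <- (a + b) / 2
      p <- ok[which.min(abs(ok - centre))]
      k <- k + 1
      rows[[k]] <- tibble(
        segment_id = sprintf("%s-%s-%03d", record$subject_id, iv$label, k),
        subject_id = record$subject_id,
        label = iv$label,
        start_s = (a - 1) / fs,
        seg24 = list(x[a:b]),
        seg1 = list(x[(p - half1):(p + half1)]),
        j_index = half1 + 1L,
        peaks = list(pk - a + 1L)
      )
    }
  }
  if (k == 0) {
    return(tibble(segment_id = character(0), subject_id = character(0),
                  label = character(0), start_s = numeric(0),
                  seg24 = list(), seg1 = list(), j_index = integer(0),
                  peaks = list()))
  }
  dplyr::bind_rows(rows)
}

#' Full preprocessing chain for one record
#'
#' Bandpass filter, artifact masking, min-max normalisation, J-peak
#' detection and paired segmentation, in that order.
#'
#' @param record A `bcg_record`.
#' @param low,high,order Bandpass settings, see [bandpass_filter()].
#' @param win_s,k_hi,k_lo Artifact settings, see [detect_artifacts()].
#' @param min_rr_s,prominence J-peak settings, see [detect_j_peaks()].
#' @return The segment-pair tibble of [segment_record()].
#' @export
#' @examples
#' rec <- render_bcg(generate_rr_series(rhythm_spec("NAF"), 40, 1), seed = 1)
#' pairs <- preprocess_record(rec)
preprocess_record <- function(record, low = 0.7, high = 10, order = 4,
                              win_s = 2, k_hi = 3, k_lo = 0.2,
                              min_rr_s = 0.4, prominence = 0.15) {
  x <- bandpass_filter(record$samples, record$fs, low, high, order)
  mask <- detect_artifacts(x, record$fs, win_s, k_hi, k_lo)
  x <- normalize_signal(x, record$fs, mask)
  peaks <- detect_j_peaks(x, record$fs, min_rr_s, prominence)
  segment_record(record, x, peaks, mask)
}

#' Preprocess every record of a cohort
#'
#' @param cohort Output of [generate_cohort()] (or a compatible list with
#'   `records`).
#' @param ... Passed to [preprocess_record()].
#' @return One combined segment-pair tibble.
#' @export
preprocess_cohort <- function(cohort, ...) {
  dplyr::bind_rows(purrr::map(cohort$records, preprocess_record, ...))
}

#' Detected RR statistics of a 24-s segment
#'
#' Coefficient of variation of the inter-peak intervals inside one window;
#' the working definition of rhythm irregularity used in class-separation
#' checks.
#'
#' @param peaks Window-relative peak indices.
#' @param fs Sampling rate in Hz.
#' @return The RR coefficient of variation, or `NA` with fewer than 3 peaks.
#' @export
segment_rr_cv <- function(peaks, fs = 125) {
  if (length(peaks) < 3) return(NA_real_)
  rr <- diff(peaks) / fs
  sd(rr) / mean(rr)
}
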