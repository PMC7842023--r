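#' Rhythm specification for the synthetic BCG generator
#'
#' Describes the beat-to-beat interval statistics of one rhythm class. Sinus
#' rhythm (`"NAF"`) has a stable mean RR interval with small Gaussian
#' variability plus a slow sinusoidal respiratory modulation; atrial
#' fibrillation (`"AF"`) is "irregularly irregular": serially uncorrelated RR
#' intervals drawn i.i.d. from a Gamma distribution with a large coefficient
#' of variation and no respiratory coupling.
#'
#' Defaults emulate a resting adult at 86 bpm with the reduced short-term
#' heart-rate variability typical of an elderly paroxysmal-AF cohort during
#' sleep. The AF coefficient of variation (0.25) is an order of magnitude
#' above the total NAF variability, so the two classes are
#' distributionally separated by construction.
#'
#' @param rhythm_class `"NAF"` or `"AF"`.
#' @param mean_rr Mean RR interval in seconds, in `[0.3, 2]`.
#' @param rr_sd NAF only: beat-to-beat Gaussian SD in seconds.
#' @param rr_cv AF only: coefficient of variation of the Gamma RR law.
#' @param resp_freq Respiratory modulation frequency in Hz.
#' @param resp_mod_depth Modulation depth as a fraction of `mean_rr`.
#' @param amp_jitter_cv Beat-amplitude jitter coefficient of variation.
#' @return A `rhythm_spec` object (named list).
#' @export
#' @examples
#' rhythm_spec("AF")
rhythm_spec <- function(rhythm_class = c("NAF", "AF"),
                        mean_rr = 0.7,
                        rr_sd = 0.015,
                        rr_cv = 0.25,
                        resp_freq = 0.25,
                        resp_mod_depth = if (rhythm_class[1] == "NAF") 0.015 else 0,
                        amp_jitter_cv = if (rhythm_class[1] == "NAF") 0.05 else 0.2) {
  if (length(rhythm_class) < 1 || !rhythm_class[1] %in% c("NAF", "AF")) {
    abort("`rhythm_class` must be \"NAF\" or \"AF\".",
          class = "bcgaf_parameter_error")
  }
  rhythm_class <- rhythm_class[1]
  check_scalar(mean_rr, "mean_rr", lower = 0.3, upper = 2)
  check_scalar(rr_sd, "rr_sd", lower = 0)
  check_scalar(rr_cv, "rr_cv", lower = 0)
  check_scalar(resp_freq, "resp_freq", lower = 0)
  check_scalar(resp_mod_depth, "resp_mod_depth", lower = 0, upper = 0.5)
  check_scalar(amp_jitter_cv, "amp_jitter_cv", lower = 0)
  structure(
    list(rhythm_class = rhythm_class, mean_rr = mean_rr, rr_sd = rr_sd,
         rr_cv = rr_cv, resp_freq = resp_freq, resp_mod_depth = resp_mod_depth,
         amp_jitter_cv = amp_jitter_cv),
    class = "rhythm_spec"
  )
}

#' @export
print.rhythm_spec <- function(x, ...) {
  cat("<rhythm_spec>", x$rhythm_class, "\n")
  cat("  mean RR:", x$mean_rr, "s;",
      if (x$rhythm_class == "NAF") paste0("rr_sd: ", x$rr_sd, " s")
      else paste0("rr_cv: ", x$rr_cv), "\n")
  cat("  resp:", x$resp_freq, "Hz x", x$resp_mod_depth,
      "; amp jitter cv:", x$amp_jitter_cv, "\n")
  invisible(x)
}

#' Beat template: the H-I-J-K-L complex as five Gaussian bumps
#'
#' A BCG heartbeat is modelled as the sum of five Gaussian deflections named
#' H, I, J, K, L, centred relative to the J wave. J must dominate in absolute
#' amplitude: the whole segmentation chain anchors on J-peaks.
#'
#' Default timings and relative amplitudes give the classic W-shaped complex
#' (small positive H, negative I, dominant positive J, negative K, small
#' positive L) whose dominant oscillation lies in the 4-8 Hz band typical of
#' mattress-sensor BCG.
#'
#' @param amplitudes Signed amplitudes of (H, I, J, K, L).
#' @param offsets Centres in seconds relative to J.
#' @param widths Gaussian SDs in seconds.
#' @return A `beat_template` object.
#' @export
beat_template <- function(amplitudes = c(H = 0.40, I = -0.85, J = 1, K = -0.90, L = 0.45),
                          offsets = c(H = -0.114, I = -0.051, J = 0, K = 0.051, L = 0.114),
                          widths = c(H = 0.064, I = 0.028, J = 0.026, K = 0.030, L = 0.072)) {
  stopifnot(length(amplitudes) == 5, length(offsets) == 5, length(widths) == 5)
  if (any(widths <= 0)) {
    abort("Template widths must be positive.", class = "bcgaf_parameter_error")
  }
  j <- which.max(abs(amplitudes))
  if (j != 3 || any(abs(amplitudes[-3]) >= abs(amplitudes[3]))) {
    abort("The J wave (third amplitude) must strictly dominate in magnitude.",
          class = "bcgaf_parameter_error")
  }
  structure(list(amplitudes = unname(amplitudes), offsets = unname(offsets),
                 widths = unname(widths)),
            class = "beat_template")
}

#' Render a beat template on a time grid
#'
#' @param template A [beat_template()].
#' @param fs Sampling rate in Hz.
#' @param span Half-width of the rendered window in seconds.
#' @return Tibble with columns `time_s` (relative to J) and `amplitude`.
#' @export
render_template <- function(template, fs = 125, span = 0.4) {
  t <- seq(-span, span, by = 1 / fs)
  a <- template_value(template, t)
  tibble(time_s = t, amplitude = a)
}

template_value <- function(template, t) {
  a <- numeric(length(t))
  for (k in 1:5) {
    a <- a + template$amplitudes[k] *
      exp(-(t - template$offsets[k])^2 / (2 * template$widths[k]^2))
  }
  a
}

# Extent of meaningful template support after/before J (4 sigma).
template_tail <- function(template) {
  max(template$offsets + 4 * template$widths)
}

#' Generate a beat-to-beat RR interval series
#'
#' NAF intervals are `mean_rr + N(0, rr_sd)` plus a sinusoidal respiratory
#' term `resp_mod_depth * mean_rr * sin(2*pi*resp_freq*t_i)` evaluated at the
#' nominal beat time `t_i = i * mean_rr`. AF intervals are i.i.d. Gamma with
#' mean `mean_rr` and coefficient of variation `rr_cv` (shape `1/rr_cv^2`),
#' hence serially uncorrelated. All intervals are clipped to at least 0.25 s.
#'
#' @param spec A [rhythm_spec()].
#' @param n_beats Number of intervals to draw (at least 2).
#' @param seed Integer seed; identical `(spec, seed)` give identical output.
#' @return Numeric vector of RR intervals in seconds.
#' @export
#' @examples
#' rr <- generate_rr_series(rhythm_spec("AF"), 10, seed = 1)
generate_rr_series <- function(spec, n_beats, seed) {
  if (!inherits(spec, "rhythm_spec")) {
    abort("`spec` must be a rhythm_spec.", class = "bcgaf_parameter_error")
  }
  if (spec$mean_rr <= 0) {
    abort("`mean_rr` must be positive.", class = "bcgaf_parameter_error")
  }
  check_scalar(n_beats, "n_beats", lower = 2)
  rr <- local_seed_eval(derive_seed(seed, "rr"), {
    if (spec$rhythm_class == "NAF") {
      t_nominal <- seq_len(n_beats) * spec$mean_rr
      spec$mean_rr +
        rnorm(n_beats, 0, spec$rr_sd) +
        spec$resp_mod_depth * spec$mean_rr *
          sin(2 * pi * spec$resp_freq * t_nominal)
    } else {
      if (spec$rr_cv <= 1e-12) {
        rep(spec$mean_rr, n_beats)
      } else {
        shape <- 1 / spec$rr_cv^2
        rgamma(n_beats, shape = shape, scale = spec$mean_rr / shape)
      }
    }
  })
  pmax(rr, 0.25)
}

#' Render a synthetic BCG record from an RR series
#'
#' Superposes one beat template at each cumulative RR time, scales each beat
#' by `1 + N(0, amp_jitter_cv)`, and adds white Gaussian noise plus a 0.3 Hz
#' sinusoidal baseline drift (the sub-passband respiratory/baseline component
#' that the 0.7 Hz highpass is later expected to remove).
#'
#' @param rr RR intervals in seconds (non-empty).
#' @param template A [beat_template()].
#' @param fs Sampling rate in Hz (>= 50).
#' @param noise_sd White-noise SD in template amplitude units.
#' @param drift_amp Amplitude of the 0.3 Hz baseline drift.
#' @param amp_jitter_cv Per-beat amplitude jitter coefficient of variation.
#' @param seed Integer seed.
#' @param subject_id Subject identifier stored in the record.
#' @param label Rhythm label (`"AF"`/`"NAF"`) for the whole record.
#' @return A `bcg_record`: list with `samples`, `fs`, `subject_id`,
#'   `label_intervals` (tibble `start_s`, `end_s`, `label`) and
#'   `true_j_peaks` (seconds).
#' @export
render_bcg <- function(rr, template = beat_template(), fs = 125,
                       noise_sd = 0.05, drift_amp = 0.1, amp_jitter_cv = 0,
                       seed = 1, subject_id = "S01", label = "NAF") {
  check_numeric_vector(rr, "rr")
  check_scalar(fs, "fs", lower = 50)
  if (!inherits(template, "beat_template")) {
    abort("`template` must be a beat_template.", class = "bcgaf_parameter_error")
  }
  beat_times <- cumsum(rr)
  duration <- sum(rr) + template_tail(template)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  scales <- local_seed_eval(derive_seed(seed, "jitter"),
                            1 + rnorm(length(beat_times), 0, amp_jitter_cv))
  x <- numeric(n)
  half <- 0.5  # template support handled within +/- 0.5 s of J
  for (b in seq_along(beat_times)) {
    tb <- beat_times[b]
    i0 <- max(1L, floor((tb - half) * fs) + 1L)
    i1 <- min(n, ceiling((tb + half) * fs) + 1L)
    idx <- i0:i1
    x[idx] <- x[idx] + scales[b] * template_value(template, t[idx] - tb)
  }
  if (noise_sd > 0) {
    x <- x + local_seed_eval(derive_seed(seed, "noise"), rnorm(n, 0, noise_sd))
  }
  if (drift_amp > 0) {
    phase <- local_seed_eval(derive_seed(seed, "drift"), runif(1, 0, 2 * pi))
    x <- x + drift_amp * sin(2 * pi * 0.3 * t + phase)
  }
  new_bcg_record(samples = x, fs = fs, subject_id = subject_id,
                 label_intervals = tibble(start_s = 0, end_s = n / fs,
                                          label = label),
                 true_j_peaks = beat_times)
}

new_bcg_record <- function(samples, fs, subject_id, label_intervals,
                           true_j_peaks = numeric(0)) {
  stopifnot(fs > 0)
  dur <- length(samples) / fs
  if (nrow(label_intervals)) {
    ok <- label_intervals$start_s >= 0 &
      label_intervals$end_s <= dur + 1e-9 &
      label_intervals$start_s < label_intervals$end_s
    if (!all(ok)) {
      abort("Label intervals must lie within the record.",
            class = "bcgaf_input_error")
    }
    o <- order(label_intervals$start_s)
    label_intervals <- label_intervals[o, ]
    if (nrow(label_intervals) > 1 &&
        any(label_intervals$start_s[-1] <
            label_intervals$end_s[-nrow(label_intervals)] - 1e-9)) {
      abort("Label intervals must not overlap.", class = "bcgaf_input_error")
    }
  }
  if (is.unsorted(true_j_peaks, strictly = TRUE) && length(true_j_peaks) > 1) {
    abort("`true_j_peaks` must be strictly increasing.",
          class = "bcgaf_input_error")
  }
  structure(list(samples = samples, fs = fs, subject_id = subject_id,
                 label_intervals = label_intervals,
                 true_j_peaks = true_j_peaks),
            class = "bcg_record")
}

#' @export
print.bcg_record <- function(x, ...) {
  cat("<bcg_record>", x$subject_id, "-",
      sprintf("%.1f s @ %g Hz,", length(x$samples) / x$fs, x$fs),
      nrow(x$label_intervals), "label interval(s),",
      length(x$true_j_peaks), "known J-peaks\n")
  invisible(x)
}

#' Inject a motion-artifact burst into a record
#'
#' Multiplies the samples of one interval by `gain`, emulating a movement or
#' out-of-bed episode; used to exercise the artifact detector.
#'
#' @param record A `bcg_record`.
#' @param start_s,dur_s Burst position and duration in seconds.
#' @param gain Amplitude multiplier (use 0 for an out-of-bed flat episode).
#' @return The modified record.
#' @export
inject_artifact_burst <- function(record, start_s, dur_s, gain = 10) {
  stopifnot(inherits(record, "bcg_record"))
  n <- length(record$samples)
  i0 <- max(1L, floor(start_s * record$fs) + 1L)
  i1 <- min(n, ceiling((start_s + dur_s) * record$fs))
  record$samples[i0:i1] <- record$samples[i0:i1] * gain
  record
}

#' Simulate a cohort of subjects with AF and NAF periods
#'
#' Each subject receives its own beat morphology: template amplitudes,
#' offsets and widths are perturbed once per subject by truncated Gaussian
#' factors (sd 10%, truncated to +/-30%), so morphology varies with subject
#' identity while class separability rests on rhythm alone. Every subject
#' contributes both rhythm classes (the simulated population is paroxysmal),
#' split so that the cohort-wide class balance is met within one segment.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param segments_per_subject 24-s segments contributed by each subject.
#' @param class_balance Fraction of AF segments, strictly in (0, 1).
#' @param seed Integer master seed.
#' @param naf_spec,af_spec Class [rhythm_spec()]s.
#' @param template Population-mean [beat_template()].
#' @param noise_sd,drift_amp Rendering noise parameters (see [render_bcg()]).
#' @param dir Optional directory; when given, records and the manifest are
#'   written as CSV and the manifest gains a `file` column.
#' @return List with `records` (named list of `bcg_record`) and `manifest`,
#'   a tibble with one row per 24-s segment: `record_id`, `subject_id`,
#'   `label`, `start_s`, `end_s` (and `file` when `dir` is given).
#' @export
#' @examples
#' co <- generate_cohort(2, 4, seed = 1)
#' co$manifest
generate_cohort <- function(n_subjects, segments_per_subject,
                            class_balance = 0.5, seed = 1,
                            naf_spec = rhythm_spec("NAF"),
                            af_spec = rhythm_spec("AF"),
                            template = beat_template(),
                            noise_sd = 0.05, drift_amp = 0.1,
                            dir = NULL) {
  check_scalar(n_subjects, "n_subjects", lower = 2)
  check_scalar(segments_per_subject, "segments_per_subject", lower = 1)
  if (!is.numeric(class_balance) || class_balance <= 0 || class_balance >= 1) {
    abort("`class_balance` must lie strictly in (0, 1).",
          class = "bcgaf_parameter_error")
  }
  total <- n_subjects * segments_per_subject
  n_af_total <- round(total * class_balance)
  # spread AF counts across subjects as evenly as possible
  base <- n_af_total %/% n_subjects
  extra <- n_af_total %% n_subjects
  n_af_by_subject <- rep(base, n_subjects) + c(rep(1, extra),
                                               rep(0, n_subjects - extra))

  records <- list()
  rows <- list()
  seg_len_s <- 24
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    subj_template <- perturb_template(template, derive_seed(seed, "subj", s))
    for (cls in c("AF", "NAF")) {
      n_seg <- if (cls == "AF") n_af_by_subject[s] else
        segments_per_subject - n_af_by_subject[s]
      if (n_seg == 0) next
      spec <- if (cls == "AF") af_spec else naf_spec
      need <- n_seg * seg_len_s + 2
      rr <- rr_series_covering(spec, need, derive_seed(seed, "rr", s, cls))
      rec_id <- paste0(sid, "-", cls)
      rec <- render_bcg(rr, template = subj_template, fs = 125,
                        noise_sd = noise_sd, drift_amp = drift_amp,
                        amp_jitter_cv = spec$amp_jitter_cv,
                        seed = derive_seed(seed, "render", s, cls),
                        subject_id = sid, label = cls)
      records[[rec_id]] <- rec
      rows[[rec_id]] <- tibble(
        record_id = rec_id, subject_id = sid, label = cls,
        start_s = (seq_len(n_seg) - 1) * seg_len_s,
        end_s = seq_len(n_seg) * seg_len_s
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- vapply(names(records), function(id) {
      path <- file.path(dir, paste0(id, ".csv"))
      write_bcg_record(records[[id]], path)
      path
    }, character(1))
    manifest$file <- unname(files[manifest$record_id])
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  }
  list(records = records, manifest = manifest)
}

# Draw enough RR intervals to cover `duration` seconds.
rr_series_covering <- function(spec, duration, seed) {
  n <- ceiling(duration / spec$mean_rr * 1.3) + 20
  rr <- generate_rr_series(spec, n, seed)
  chunk <- 1L
  while (sum(rr) < duration) {
    chunk <- chunk + 1L
    rr <- c(rr, generate_rr_series(spec, n, derive_seed(seed, "more", chunk)))
  }
  keep <- which(cumsum(rr) >= duration)[1]
  rr[seq_len(keep)]
}

# Per-subject morphology: amplitudes vary freely (sd 10%, truncated +/-30%);
# wave timings and widths vary less (sd 3%, truncated +/-7.5%) because they
# set the dominant oscillation frequency that embedding-delay estimation
# keys on, and carrier timing is far more stable across subjects than
# amplitude in mattress BCG.
perturb_template <- function(template, seed) {
  local_seed_eval(seed, {
    fac <- function(k, sd, lim) pmin(pmax(1 + rnorm(k, 0, sd), 1 - lim), 1 + lim)
    amp <- template$amplitudes * fac(5, 0.10, 0.30)
    # keep J strictly dominant regardless of the draw
    amp[3] <- sign(amp[3]) * max(abs(amp[3]), 1.15 * max(abs(amp[-3])))
    beat_template(amplitudes = amp,
                  offsets = template$offsets * fac(5, 0.03, 0.075),
                  widths = template$widths * fac(5, 0.03, 0.075))
  })
}
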