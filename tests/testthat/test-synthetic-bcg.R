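test_that("NAF RR series match their specified moments", {
  spec <- rhythm_spec("NAF", mean_rr = 0.8, rr_sd = 0.04, resp_mod_depth = 0)
  rr <- generate_rr_series(spec, 10000, seed = 1)
  expect_equal(mean(rr), 0.8, tolerance = 0.01 / 0.8)
  expect_lt(sd(rr) / mean(rr), 0.08)
  expect_true(all(rr > 0.25))
})

test_that("AF RR series are Gamma-dispersed and serially uncorrelated", {
  spec <- rhythm_spec("AF", mean_rr = 0.8, rr_cv = 0.25)
  rr <- generate_rr_series(spec, 10000, seed = 1)
  cv <- sd(rr) / mean(rr)
  expect_gt(cv, 0.2)
  expect_lt(cv, 0.3)
  lag1 <- cor(rr[-1], rr[-length(rr)])
  expect_lt(abs(lag1), 0.05)
})

test_that("degenerate noise settings give a constant RR series", {
  naf <- rhythm_spec("NAF", mean_rr = 0.8, rr_sd = 0, resp_mod_depth = 0)
  expect_equal(generate_rr_series(naf, 50, seed = 3), rep(0.8, 50))
  af <- rhythm_spec("AF", mean_rr = 0.8, rr_cv = 0)
  expect_equal(generate_rr_series(af, 50, seed = 3), rep(0.8, 50))
})

test_that("rhythm parameters are validated", {
  expect_error(rhythm_spec("SR"), class = "bcgaf_parameter_error")
  expect_error(rhythm_spec("NAF", mean_rr = 0.1),
               class = "bcgaf_parameter_error")
  expect_error(generate_rr_series(list(), 10, 1),
               class = "bcgaf_parameter_error")
})

test_that("default AF and NAF specs are distributionally separated", {
  naf <- rhythm_spec("NAF")
  af <- rhythm_spec("AF")
  expect_gte(af$rr_cv, 2 * naf$rr_sd / naf$mean_rr)
})

test_that("the rendered template peaks at the nominal J time", {
  tpl <- render_template(beat_template(), fs = 1000, span = 0.4)
  expect_lte(abs(tpl$time_s[which.max(tpl$amplitude)]), 0.008)
  expect_error(beat_template(amplitudes = c(1, -2, 1.5, -0.5, 0.2)),
               class = "bcgaf_parameter_error")
})

test_that("noiseless rendering places signal maxima at the true J peaks", {
  rr <- rep(0.8, 5)
  rec <- render_bcg(rr, fs = 125, noise_sd = 0, drift_amp = 0,
                    amp_jitter_cv = 0, seed = 1)
  expect_equal(diff(rec$true_j_peaks), rep(0.8, 4))
  for (tb in rec$true_j_peaks) {
    win <- round(tb * 125) + 1 + (-20:20)
    win <- win[win >= 1 & win <= length(rec$samples)]
    local_max <- win[which.max(rec$samples[win])]
    expect_lte(abs(local_max - 1 - tb * 125), 1)
  }
})

test_that("record duration equals the RR sum plus the template tail", {
  rr <- generate_rr_series(rhythm_spec("NAF"), 30, seed = 5)
  rec <- render_bcg(rr, fs = 125, seed = 5)
  expected <- sum(rr) + max(beat_template()$offsets +
                              4 * beat_template()$widths)
  expect_lte(abs(length(rec$samples) / 125 - expected), 1 / 125)
})

test_that("a regular-rhythm record has a harmonic comb at the heart rate", {
  # the beat template carries its energy near the 5-9 Hz carrier, so the
  # periodicity of the rhythm appears as a comb of spectral lines spaced
  # at the heart rate: every dominant line must sit on a multiple of
  # 1/mean_rr
  spec <- rhythm_spec("NAF", rr_sd = 0, resp_mod_depth = 0)
  rr <- generate_rr_series(spec, 60, seed = 2)
  rec <- render_bcg(rr, fs = 125, noise_sd = 0.05, drift_amp = 0.1,
                    amp_jitter_cv = 0, seed = 2)
  x <- bandpass_filter(rec$samples, 125)
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
  freqs <- sp$freq * 125
  f0 <- 1 / spec$mean_rr
  top <- freqs[order(sp$spec, decreasing = TRUE)[1:5]]
  offsets <- abs(top / f0 - round(top / f0)) * f0
  expect_lt(max(offsets), 0.1)
  # and the heart-rate line itself stands far above the local noise floor
  line <- max(sp$spec[abs(freqs - f0) < 0.1])
  floor_ <- median(sp$spec[freqs > 0.8 & freqs < 3])
  expect_gt(line / floor_, 10)
})

test_that("cohort manifests count subjects, segments and classes correctly", {
  co <- generate_cohort(10, 20, class_balance = 0.5, seed = 9,
                        noise_sd = 0, drift_amp = 0)
  expect_equal(nrow(co$manifest), 200)
  expect_equal(sum(co$manifest$label == "AF"), 100)
  expect_equal(sum(co$manifest$label == "NAF"), 100)
  expect_equal(length(unique(co$manifest$subject_id)), 10)
  # every row lies inside its record's label interval
  for (i in sample(nrow(co$manifest), 20)) {
    row <- co$manifest[i, ]
    rec <- co$records[[row$record_id]]
    expect_lte(row$end_s, length(rec$samples) / rec$fs + 1e-9)
    expect_equal(rec$label_intervals$label[1], row$label)
  }
})

test_that("identical seeds reproduce cohorts exactly", {
  a <- generate_cohort(3, 4, seed = 77)
  b <- generate_cohort(3, 4, seed = 77)
  expect_identical(a$manifest, b$manifest)
  expect_identical(lapply(a$records, function(r) r$samples),
                   lapply(b$records, function(r) r$samples))
  c2 <- generate_cohort(3, 4, seed = 78)
  expect_false(identical(a$records[[1]]$samples, c2$records[[1]]$samples))
})

test_that("class balance outside (0,1) is rejected", {
  expect_error(generate_cohort(3, 4, class_balance = 0, seed = 1),
               class = "bcgaf_parameter_error")
  expect_error(generate_cohort(3, 4, class_balance = 1.2, seed = 1),
               class = "bcgaf_parameter_error")
})

test_that("AF and NAF detected RR variability distributions are disjoint", {
  pairs <- fixture_pairs()
  cv <- vapply(pairs$peaks, segment_rr_cv, numeric(1))
  af <- pairs$label == "AF"
  expect_gt(quantile(cv[af], 0.05, na.rm = TRUE),
            quantile(cv[!af], 0.95, na.rm = TRUE))
})
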