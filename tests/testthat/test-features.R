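# Feature extraction: latency, ISI histogram, burst index, derivative,
# AHP metric, firing rate, and the bundled extractor.

test_that("trough-to-peak latency counts samples between trough and first peak", {
  # trough at sample index 41, first local max at 47 -> 6 samples = 0.30 ms
  wf <- waveform_from_knots(c(1, 30, 41, 47, 55, 64),
                            c(0, 0, -120, 40, -5, 0), n = 64)
  expect_equal(trough_to_peak_latency(wf, interpolate = FALSE), 0.30)
})

test_that("degenerate waveforms raise classed errors", {
  # monotonic decay: no post-trough local maximum (trough at boundary)
  wf_decay <- waveform_template(seq(0, -100, length.out = 32))
  expect_error(trough_to_peak_latency(wf_decay, flip = FALSE),
               class = "dg_degenerate_waveform")
  # trough followed by pure monotone decay to a deeper-than-peak level
  wf_flat <- waveform_from_knots(c(1, 10, 32), c(0, -100, -99.9), n = 32)
  expect_error(trough_to_peak_latency(wf_flat, flip = FALSE),
               class = "dg_degenerate_waveform")
})

test_that("inverted-polarity waveforms are flipped with a warning", {
  wf <- waveform_from_knots(c(1, 10, 16, 40), c(0, 120, -40, 0), n = 40)
  expect_warning(ttp <- trough_to_peak_latency(wf, interpolate = FALSE),
                 "polarity")
  expect_equal(ttp, 6 * 0.05)
})

test_that("latency and burst index are amplitude-invariant; AHP scales linearly", {
  wf <- generate_waveform(waveform_params(0.5, ahp_slope_uv_per_ms = 80))
  wf2 <- wf
  wf2$samples <- wf$samples * 2
  expect_equal(trough_to_peak_latency(wf2), trough_to_peak_latency(wf))
  expect_equal(ahp_derivative_metric(wf2), 2 * ahp_derivative_metric(wf),
               tolerance = 1e-10)
})

test_that("first derivative: constant, linear ramp, and linearity", {
  flat <- waveform_template(rep(5, 20))
  expect_equal(first_derivative(flat), rep(0, 20))
  ramp <- waveform_template(seq_len(20))  # 1 uV per sample at 20 kHz
  d <- first_derivative(ramp)
  expect_equal(d, rep(20, 20))            # 1 uV / 0.05 ms
  wf <- generate_waveform(waveform_params(0.5))
  wf2 <- wf
  wf2$samples <- wf$samples * 2
  expect_equal(first_derivative(wf2), 2 * first_derivative(wf))
})

test_that("AHP metric is zero for a flat tail and errors on a too-short window", {
  # descend, rise to a peak, then perfectly flat tail
  wf <- waveform_from_knots(c(1, 10, 20, 26, 64),
                            c(0, 0, -120, 40, 40), n = 64)
  expect_equal(ahp_derivative_metric(wf), 0)
  # peak too close to the end: AHP window under 3 samples
  wf2 <- waveform_from_knots(c(1, 14, 19, 20), c(0, -120, 40, 39), n = 20)
  expect_error(ahp_derivative_metric(wf2), class = "dg_degenerate_waveform")
})

test_that("ISI histogram counts intervals per bin and excludes out-of-range ISIs", {
  tr <- train_from_isis_ms(c(5, 5, 250, 400))
  h <- isi_histogram(tr, bin_width_ms = 1)
  expect_equal(h$counts[6], 2)     # bin [5, 6) ms
  expect_equal(h$counts[251], 1)   # bin [250, 251) ms
  expect_equal(sum(h$counts), 3)   # the 400 ms ISI is excluded
  expect_equal(h$n_isi, 4)
  single <- spike_train(0.5, duration_s = 10)
  expect_true(all(isi_histogram(single)$counts == 0))
})

test_that("ISI histogram totals equal a brute-force recount on random trains", {
  for (seed in 1:100) {
    tr <- random_train(seed, duration_s = 10)
    h <- isi_histogram(tr)
    isis_ms <- diff(tr$times_s) * 1000
    expect_identical(sum(h$counts), sum(isis_ms < 300))
  }
})

test_that("burst index follows the windowed-frequency definition and edge rules", {
  # 30 ISIs at 5 ms and 20 at 250 ms: (30/10) / (20/100) = 15
  tr <- train_from_isis_ms(c(rep(5, 30), rep(250, 20)))
  expect_equal(as.numeric(burst_index(tr)), 15)
  expect_equal(as.numeric(burst_index(tr, normalize = "raw")), 30 / 20)
  # all ISIs at 100 ms: both windows empty -> 0 by the zero-numerator rule
  expect_equal(as.numeric(burst_index(train_from_isis_ms(rep(100, 50)))), 0)
  # bursting with an empty late window -> +Inf, flagged
  bi <- burst_index(train_from_isis_ms(rep(4, 400)))
  expect_identical(as.numeric(bi), Inf)
  expect_identical(attr(bi, "flags"), "infinite_bi")
  # fewer than 2 spikes -> 0 with a quality flag, not an error
  bi1 <- burst_index(spike_train(1, duration_s = 10))
  expect_identical(as.numeric(bi1), 0)
  expect_identical(attr(bi1, "flags"), "few_spikes")
})

test_that("mean firing rate is count over duration, matching a recount", {
  expect_equal(mean_firing_rate(spike_train(seq(0.05, 9.95, length.out = 100),
                                            10)), 10)
  expect_equal(mean_firing_rate(spike_train(numeric(0), 10)), 0)
  for (seed in 1:50) {
    tr <- random_train(seed, duration_s = 5)
    expect_identical(mean_firing_rate(tr),
                     length(tr$times_s) / tr$duration_s)
  }
})

test_that("extract_features bundles features and propagates quality flags", {
  wf <- generate_waveform(waveform_params(0.25, ahp_slope_uv_per_ms = 100))
  tr <- generate_spike_train(train_params("regular", rate_hz = 15,
                                          duration_s = 120, seed = 3))
  f <- extract_features(wf, tr)
  expect_s3_class(f, "unit_features")
  expect_lt(abs(f$trough_to_peak_ms - 0.25), 0.02)
  expect_lt(abs(f$ahp_uv_per_ms - 100) / 100, 0.05)
  expect_equal(f$burst_index, 0)
  expect_length(f$flags, 0)

  # one-spike unit: rate defined, BI zero and flagged, latency computed
  f1 <- extract_features(wf, spike_train(1, duration_s = 10))
  expect_equal(f1$firing_rate_hz, 0.1)
  expect_equal(f1$burst_index, 0)
  expect_true("few_spikes" %in% f1$flags)
  expect_false(is.na(f1$trough_to_peak_ms))

  # degenerate waveform: flagged, not fatal
  f2 <- suppressWarnings(
    extract_features(waveform_template(seq(0, -100, length.out = 32)), tr))
  expect_true("degenerate_waveform" %in% f2$flags)
  expect_true(is.na(f2$trough_to_peak_ms))
  expect_false(is.na(f2$firing_rate_hz))
})
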