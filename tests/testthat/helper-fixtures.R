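# Shared fixtures, all built in code.

# Spike train from a vector of inter-spike intervals (ms).
train_from_isis_ms <- function(isis_ms, pad_s = 1) {
  times <- cumsum(c(0.5, isis_ms / 1000))
  spike_train(times, duration_s = max(times) + pad_s)
}

# Piecewise-linear waveform through (index, value) knots, 1-based indices.
waveform_from_knots <- function(knots_idx, knots_val, n,
                                sampling_rate_hz = 20000) {
  v <- approx(knots_idx, knots_val, xout = seq_len(n), rule = 2)$y
  waveform_template(v, sampling_rate_hz)
}

# Brute-force burst index: explicit loop over successive ISIs, independent
# of the histogram implementation.
bi_bruteforce <- function(train, normalize = "per_ms") {
  tt <- train$times_s
  if (length(tt) < 2L) return(0)
  early <- 0L
  late <- 0L
  for (i in 2:length(tt)) {
    isi_ms <- (tt[i] - tt[i - 1L]) * 1000
    if (isi_ms >= 0 && isi_ms < 10) early <- early + 1L
    if (isi_ms >= 200 && isi_ms < 300) late <- late + 1L
  }
  if (early == 0L) return(0)
  if (late == 0L) return(Inf)
  if (normalize == "per_ms") (early / 10) / (late / 100) else early / late
}

# A random spike train mixing regimes, for property sweeps.
random_train <- function(seed, duration_s = 20) {
  set.seed(seed)
  mode <- sample(c("poisson", "bursty", "regular"), 1)
  rate <- runif(1, 0.5, 12)
  generate_spike_train(train_params(mode, rate_hz = rate,
                                    duration_s = duration_s, seed = seed))
}

# Triangular action-potential sweep with exactly known properties:
# slow 10 mV/ms approach to threshold, linear rise and fall.
triangle_ap_sweep <- function(threshold_mv = -50, peak_mv = 30,
                              rise_ms = 1, fall_ms = 1, end_mv = -50,
                              fs = 50000, baseline_mv = -70) {
  t0 <- 20  # onset (ms)
  kt <- c(0, t0 - 2, t0, t0 + rise_ms, t0 + rise_ms + fall_ms,
          t0 + rise_ms + fall_ms + 5, 40)
  kv <- c(baseline_mv, baseline_mv, threshold_mv, peak_mv, end_mv,
          baseline_mv, baseline_mv)
  n <- round(40e-3 * fs)
  v <- approx(kt / 1000, kv, xout = (seq_len(n) - 1) / fs, rule = 2)$y
  current_clamp_sweep(v, fs, injected_current_pa = 200,
                      baseline_mv = baseline_mv)
}
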