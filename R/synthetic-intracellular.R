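# Synthetic current-clamp sweeps: square current steps from a -70 mV
# baseline with stylized action potentials placed according to a
# threshold-linear frequency-current relationship.

#' Action-potential shape parameters for synthetic sweeps
#'
#' The AP is piecewise linear: a slow approach to threshold, a fast linear
#' upstroke, a slower linear downstroke overshooting into the
#' afterhyperpolarization, and a slow recovery.  With a fall rate at half
#' the rise rate, the threshold-referenced half-amplitude width is
#' `half_width_ms` exactly.
#'
#' @param threshold_mv voltage threshold (default -45).
#' @param amplitude_mv threshold-to-peak amplitude (default 80).
#' @param half_width_ms half-amplitude width (default 1).
#' @param ahp_mv afterhyperpolarization depth below threshold (default 10).
#' @param fall_rise_ratio rise rate / fall rate (default 2).
#' @return A list of class `ap_shape`.
#' @export
ap_shape_params <- function(threshold_mv = -45, amplitude_mv = 80,
                            half_width_ms = 1, ahp_mv = 10,
                            fall_rise_ratio = 2) {
  assert_scalar(amplitude_mv, "amplitude_mv", lower = 0, strict_lower = TRUE)
  assert_scalar(half_width_ms, "half_width_ms", lower = 0, strict_lower = TRUE)
  assert_scalar(ahp_mv, "ahp_mv", lower = 0)
  assert_scalar(fall_rise_ratio, "fall_rise_ratio", lower = 0,
                strict_lower = TRUE)
  structure(list(threshold_mv = threshold_mv, amplitude_mv = amplitude_mv,
                 half_width_ms = half_width_ms, ahp_mv = ahp_mv,
                 fall_rise_ratio = fall_rise_ratio),
            class = "ap_shape")
}

#' Generate synthetic current-clamp sweeps
#'
#' One sweep per injected current.  The spike count of each sweep is
#' `round(max(0, f_i_slope * (I - rheobase)) * step_duration_s)`, with
#' spikes placed evenly across the step window; each spike is a piecewise
#' linear action potential with the stated shape.
#'
#' @param step_pa_list injected currents in pA (nonnegative).
#' @param f_i_slope_hz_per_pa slope of the frequency-current curve above
#'   rheobase (default 0.2 Hz/pA).
#' @param rheobase_pa rheobase current (default 100 pA).
#' @param ap_shape an [ap_shape_params()] object.
#' @param step_duration_s duration of the current step (default 0.5 s).
#' @param pre_s,post_s baseline before/after the step (default 0.1 s each).
#' @param baseline_mv holding potential (default -70 mV).
#' @param sampling_rate_hz sampling rate (default 50000).
#' @param noise_sd_mv additive voltage noise (default 0).
#' @param seed integer seed.
#' @return A list of class `sweep_set`: `sweeps` (list of
#'   [current_clamp_sweep()] objects ordered as `step_pa_list`) and
#'   `truth` data frame (`current_pa`, `n_spikes`, `rate_hz`,
#'   `onset_times_s` as a list column).
#' @export
generate_intracellular_sweeps <- function(step_pa_list = seq(0, 400, by = 100),
                                          f_i_slope_hz_per_pa = 0.2,
                                          rheobase_pa = 100,
                                          ap_shape = ap_shape_params(),
                                          step_duration_s = 0.5,
                                          pre_s = 0.1, post_s = 0.1,
                                          baseline_mv = -70,
                                          sampling_rate_hz = 50000,
                                          noise_sd_mv = 0,
                                          seed = 1L) {
  if (!length(step_pa_list) || any(step_pa_list < 0)) {
    dg_stop("`step_pa_list` must be nonnegative currents")
  }
  assert_scalar(f_i_slope_hz_per_pa, "f_i_slope_hz_per_pa", lower = 0)
  assert_scalar(rheobase_pa, "rheobase_pa", lower = 0)
  assert_scalar(step_duration_s, "step_duration_s", lower = 0,
                strict_lower = TRUE)
  assert_scalar(noise_sd_mv, "noise_sd_mv", lower = 0)
  stopifnot(inherits(ap_shape, "ap_shape"))

  sh <- ap_shape
  rise_rate <- sh$amplitude_mv * (1 + sh$fall_rise_ratio) /
    (2 * sh$half_width_ms)                      # mV/ms
  fall_rate <- rise_rate / sh$fall_rise_ratio
  rise_ms <- sh$amplitude_mv / rise_rate
  fall_ms <- (sh$amplitude_mv + sh$ahp_mv) / fall_rate
  v_inter <- sh$threshold_mv - 8               # inter-spike plateau
  footprint_ms <- 2 + rise_ms + fall_ms + 3    # approach + AP + recovery

  fs <- sampling_rate_hz
  total_s <- pre_s + step_duration_s + post_s
  n <- round(total_s * fs)
  t_s <- (seq_len(n) - 1) / fs

  sweeps <- vector("list", length(step_pa_list))
  truth_rows <- vector("list", length(step_pa_list))
  for (i in seq_along(step_pa_list)) {
    current <- step_pa_list[i]
    n_sp <- round(max(0, f_i_slope_hz_per_pa * (current - rheobase_pa)) *
                    step_duration_s)
    if (n_sp > 0 && step_duration_s * 1000 / n_sp < footprint_ms + 2) {
      dg_stop(sprintf(
        "requested firing rate at %g pA leaves no room between action potentials",
        current))
    }
    # knot points (time ms, voltage mV) for linear interpolation
    on_ms <- pre_s * 1000
    off_ms <- (pre_s + step_duration_s) * 1000
    kt <- c(0, on_ms, on_ms + 0.2)
    kv <- c(baseline_mv, baseline_mv, if (n_sp > 0 || current > 0)
      v_inter else baseline_mv)
    onsets_ms <- if (n_sp > 0) {
      on_ms + (seq_len(n_sp) - 0.5) * step_duration_s * 1000 / n_sp
    } else numeric(0)
    for (t0 in onsets_ms) {
      kt <- c(kt, t0 - 2, t0, t0 + rise_ms, t0 + rise_ms + fall_ms,
              t0 + rise_ms + fall_ms + 3)
      kv <- c(kv, v_inter, sh$threshold_mv,
              sh$threshold_mv + sh$amplitude_mv,
              sh$threshold_mv - sh$ahp_mv, v_inter)
    }
    kt <- c(kt, off_ms, off_ms + 0.5, total_s * 1000)
    kv <- c(kv, kv[length(kv)], baseline_mv, baseline_mv)
    v <- stats::approx(kt / 1000, kv, xout = t_s, rule = 2, ties = "ordered")$y
    if (noise_sd_mv > 0) {
      v <- v + with_seed(seed + i, stats::rnorm(n, 0, noise_sd_mv))
    }
    sweeps[[i]] <- current_clamp_sweep(
      voltage_mv = v, sampling_rate_hz = fs, injected_current_pa = current,
      baseline_mv = baseline_mv,
      step_window_s = c(pre_s, pre_s + step_duration_s))
    truth_rows[[i]] <- data.frame(current_pa = current, n_spikes = n_sp,
                                  rate_hz = n_sp / step_duration_s)
    truth_rows[[i]]$onset_times_s <- I(list(onsets_ms / 1000))
  }
  structure(list(sweeps = sweeps, truth = do.call(rbind, truth_rows),
                 ap_shape = sh),
            class = "sweep_set")
}
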