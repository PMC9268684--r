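# Current-clamp analysis: spike detection, F-I curves, first-AP
# properties, and recovery of generator ground truth.

test_that("flat sweeps contain no spikes; criterion above max dV/dt finds none", {
  flat <- current_clamp_sweep(rep(-70, 5000), 50000, 0)
  expect_equal(nrow(detect_spikes_intracellular(flat)), 0)
  sw <- triangle_ap_sweep()
  expect_equal(nrow(detect_spikes_intracellular(sw)), 1)
  expect_equal(nrow(detect_spikes_intracellular(sw, 1e5)), 0)
})

test_that("generator sweeps are detected at their ground-truth onsets", {
  ss <- generate_intracellular_sweeps(step_pa_list = c(200, 300), seed = 5)
  for (i in seq_along(ss$sweeps)) {
    det <- detect_spikes_intracellular(ss$sweeps[[i]])
    truth <- ss$truth$onset_times_s[[i]]
    expect_equal(nrow(det), length(truth))
    if (length(truth)) {
      expect_true(all(abs(det$time_s - truth) < 2e-4))
    }
  }
})

test_that("the F-I curve matches the generator's threshold-linear rule", {
  ss <- generate_intracellular_sweeps(step_pa_list = seq(0, 400, 100),
                                      f_i_slope_hz_per_pa = 0.2,
                                      rheobase_pa = 100, seed = 2)
  fi <- fi_curve(ss)
  expect_equal(fi$rate_hz, c(0, 0, 20, 40, 60))       # 0.2*(I-100) Hz
  expect_true(all(diff(fi$rate_hz) >= 0))             # monotone
  # permuting sweep order leaves the curve unchanged
  fi2 <- fi_curve(ss$sweeps[c(3, 1, 5, 2, 4)])
  expect_equal(fi2, fi)
})

test_that("duplicate currents are aggregated by mean with a warning", {
  ss <- generate_intracellular_sweeps(step_pa_list = c(200, 200), seed = 9)
  expect_warning(fi <- fi_curve(ss), "duplicate")
  expect_equal(nrow(fi), 1)
  expect_equal(fi$rate_hz, 20)
})

test_that("a symmetric triangular AP has half-width exactly 1 ms", {
  # threshold -50 mV, peak +30 mV (amplitude 80), 1 ms rise, 1 ms fall:
  # the half-amplitude crossings span half the base (similar triangles)
  sw <- triangle_ap_sweep(threshold_mv = -50, peak_mv = 30,
                          rise_ms = 1, fall_ms = 1)
  ap <- ap_properties(sw)
  expect_equal(ap$half_width_ms, 1.0, tolerance = 0.02)
  expect_equal(ap$amplitude_mv, 80, tolerance = 1)
  expect_equal(ap$threshold_mv, -50, tolerance = 1)
})

test_that("AP properties recover generator shapes within 5% at zero noise", {
  for (amp in c(60, 80, 100)) {
    for (hw in c(0.6, 1.0, 1.4)) {
      ss <- generate_intracellular_sweeps(
        step_pa_list = 300,
        ap_shape = ap_shape_params(amplitude_mv = amp, half_width_ms = hw,
                                   ahp_mv = 10),
        seed = 1)
      ap <- ap_properties(ss$sweeps[[1]])
      expect_lt(abs(ap$amplitude_mv - amp) / amp, 0.05)
      expect_lt(abs(ap$half_width_ms - hw) / hw, 0.05)
      expect_lt(abs(ap$ahp_mv - 10) / 10, 0.05)
      expect_lt(abs(ap$threshold_mv - (-45)), 1)
    }
  }
})

test_that("time dilation scales the half-width exactly", {
  sw <- triangle_ap_sweep()
  slow <- current_clamp_sweep(sw$voltage_mv, sw$sampling_rate_hz / 2,
                              sw$injected_current_pa)
  hw1 <- ap_properties(sw)$half_width_ms
  # halving the sampling rate doubles every duration; the dV/dt criterion
  # is halved so the same samples cross it
  hw2 <- ap_properties(slow, dvdt_threshold_mv_per_ms = 10)$half_width_ms
  expect_equal(hw2, 2 * hw1, tolerance = 1e-10)
})

test_that("sweeps without spikes raise a no-AP error", {
  ss <- generate_intracellular_sweeps(step_pa_list = 50, seed = 3)
  expect_equal(fi_curve(ss)$rate_hz, 0)
  expect_error(ap_properties(ss$sweeps[[1]]), class = "dg_no_ap")
})

test_that("sweep generation is deterministic given the seed", {
  a <- generate_intracellular_sweeps(step_pa_list = 300, noise_sd_mv = 0.3,
                                     seed = 77)
  b <- generate_intracellular_sweeps(step_pa_list = 300, noise_sd_mv = 0.3,
                                     seed = 77)
  expect_identical(a$sweeps[[1]]$voltage_mv, b$sweeps[[1]]$voltage_mv)
})
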