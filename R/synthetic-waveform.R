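# Synthetic mean-waveform generator with exact, calibrated ground truth.
#
# Template family: a sum of three Gaussian lobes -- a deep negative trough
# lobe, a positive repolarization peak lobe, and a shallow slow negative
# afterhyperpolarization (AHP) undershoot.  The family is smooth, so
# sub-sample parabolic interpolation of extrema is well behaved, and the
# lobe centers / peak amplitude are calibrated numerically at generation
# time so that the *continuous* template's trough-to-peak latency and
# post-peak maximum |dV/dt| equal the requested ground truth to ~1e-5
# precision.  Measured features then differ from ground truth only through
# sampling.

#' Parameters for a synthetic spike waveform
#'
#' @param trough_to_peak_ms target trough-to-peak latency in ms
#'   (0 < value, and at least 2 ms shorter than `total_duration_ms`).
#' @param trough_amplitude_uv trough amplitude in uV; must be negative
#'   (extracellular spikes are negative-going). Default -150.
#' @param ahp_slope_uv_per_ms target post-peak maximum |dV/dt| in uV/ms;
#'   must be strictly positive (a smooth template with a genuine positive
#'   peak cannot have an exactly zero post-peak derivative). Default 90.
#' @param total_duration_ms waveform duration in ms (default 3).
#' @param sampling_rate_hz sampling rate in Hz (default 20000).
#' @param noise_sd_uv standard deviation of additive white noise in uV
#'   (default 0).
#' @return A validated list of class `waveform_params`.
#' @seealso [generate_waveform()]
#' @export
waveform_params <- function(trough_to_peak_ms,
                            trough_amplitude_uv = -150,
                            ahp_slope_uv_per_ms = 90,
                            total_duration_ms = 3,
                            sampling_rate_hz = 20000,
                            noise_sd_uv = 0) {
  assert_scalar(trough_to_peak_ms, "trough_to_peak_ms", lower = 0,
                strict_lower = TRUE)
  assert_scalar(trough_amplitude_uv, "trough_amplitude_uv", upper = 0,
                strict_upper = TRUE)
  assert_scalar(ahp_slope_uv_per_ms, "ahp_slope_uv_per_ms", lower = 0,
                strict_lower = TRUE)
  assert_scalar(total_duration_ms, "total_duration_ms", lower = 0,
                strict_lower = TRUE)
  assert_scalar(sampling_rate_hz, "sampling_rate_hz", lower = 0,
                strict_lower = TRUE)
  assert_scalar(noise_sd_uv, "noise_sd_uv", lower = 0)
  if (trough_to_peak_ms + 2 > total_duration_ms) {
    dg_stop("total_duration_ms must exceed trough_to_peak_ms by at least 2 ms")
  }
  structure(
    list(trough_to_peak_ms = trough_to_peak_ms,
         trough_amplitude_uv = trough_amplitude_uv,
         ahp_slope_uv_per_ms = ahp_slope_uv_per_ms,
         total_duration_ms = total_duration_ms,
         sampling_rate_hz = sampling_rate_hz,
         noise_sd_uv = noise_sd_uv),
    class = "waveform_params"
  )
}

# Gaussian lobe and its time derivative.
.gauss <- function(t, c, s) exp(-((t - c)^2) / (2 * s^2))
.dgauss <- function(t, c, s) -((t - c) / s^2) * exp(-((t - c)^2) / (2 * s^2))

.wf_eval <- function(t, sh) {
  v <- 0
  for (k in seq_along(sh$amps)) {
    v <- v + sh$amps[k] * .gauss(t, sh$centers[k], sh$sigmas[k])
  }
  v
}

.wf_eval_deriv <- function(t, sh) {
  d <- 0
  for (k in seq_along(sh$amps)) {
    d <- d + sh$amps[k] * .dgauss(t, sh$centers[k], sh$sigmas[k])
  }
  d
}

# Calibrate lobe centers and peak amplitude so that the continuous template
# has its trough at t_tr, its first post-trough maximum at t_tr + ttp, and
# post-peak max |dV/dt| equal to the requested slope.  Fixed-point
# iteration; each update shifts centers by the residual extremum error and
# rescales the peak amplitude multiplicatively.
.calibrate_waveform <- function(ttp, trough_amp_uv, ahp_slope, total_ms) {
  a1 <- abs(trough_amp_uv)
  s1 <- min(max(0.3 * ttp, 0.045), 0.2)   # trough lobe width (ms)
  s2 <- min(max(0.5 * ttp, 0.2), 0.3)     # peak/repolarization lobe width
  s3 <- 0.35                              # slow undershoot width
  ufrac <- 0.15                           # undershoot amplitude fraction
  t_tr <- min(1.0, 0.4 * total_ms)

  c1 <- t_tr
  c2 <- t_tr + ttp
  a2 <- ahp_slope * s2 * sqrt(exp(1))
  tf <- seq(0, total_ms, by = 0.002)
  dtf <- 0.002
  converged <- FALSE

  for (it in seq_len(80L)) {
    c3 <- min(c2 + 0.8, total_ms - 0.25)
    sh <- list(amps = c(-a1, a2, -ufrac * a2),
               centers = c(c1, c2, c3),
               sigmas = c(s1, s2, s3))
    v <- .wf_eval(tf, sh)
    i_tr <- which.min(v)
    if (i_tr <= 1L || i_tr >= length(tf)) {
      dg_stop("waveform calibration failed: trough at template boundary")
    }
    t_trough <- tf[i_tr] + dtf * parabolic_vertex(v[i_tr - 1], v[i_tr], v[i_tr + 1])

    post <- (i_tr + 1L):length(tf)
    i_pk <- post[which.max(v[post])]
    if (i_pk >= length(tf)) {
      dg_stop("waveform calibration failed: peak at template boundary")
    }
    t_peak <- tf[i_pk] + dtf * parabolic_vertex(v[i_pk - 1], v[i_pk], v[i_pk + 1])

    d <- .wf_eval_deriv(tf, sh)
    win <- which(tf > t_peak)
    if (length(win) < 3L) dg_stop("waveform calibration failed: empty AHP window")
    j <- win[which.max(abs(d[win]))]
    m <- if (j > 1L && j < length(tf)) {
      parabolic_peak_value(abs(d[j - 1]), abs(d[j]), abs(d[j + 1]))
    } else {
      abs(d[j])
    }

    e1 <- t_tr - t_trough
    e2 <- (t_tr + ttp) - t_peak
    r <- ahp_slope / m
    c1 <- c1 + e1
    c2 <- c2 + e2
    a2 <- a2 * r
    if (abs(e1) < 1e-5 && abs(e2) < 1e-5 && abs(r - 1) < 1e-5) {
      converged <- TRUE
      break
    }
    if (!is.finite(a2) || a2 <= 0 || a2 > 10 * a1) {
      dg_stop("waveform calibration diverged: AHP slope target infeasible for this trough amplitude")
    }
  }
  if (!converged) {
    dg_stop("waveform calibration did not converge for the requested parameters")
  }
  if (a2 >= 0.85 * a1) {
    dg_stop("AHP slope target too large: peak amplitude would rival the trough")
  }
  list(amps = c(-a1, a2, -ufrac * a2),
       centers = c(c1, c2, min(c2 + 0.8, total_ms - 0.25)),
       sigmas = c(s1, s2, s3),
       t_trough_ms = t_tr, t_peak_ms = t_tr + ttp)
}

#' Generate a synthetic mean spike waveform
#'
#' Builds a smooth three-lobe template (negative trough, positive peak,
#' slow AHP undershoot) whose continuous trough-to-peak latency and
#' post-peak maximum |dV/dt| are calibrated to the requested ground truth,
#' samples it at the requested rate and optionally adds white noise.
#'
#' At zero noise the measured trough-to-peak latency agrees with
#' `trough_to_peak_ms` within half a sample period, and
#' [ahp_derivative_metric()] recovers `ahp_slope_uv_per_ms` within 5%.
#'
#' @param params a [waveform_params()] object.
#' @param seed integer seed for the additive noise (ignored at zero noise).
#' @return A [waveform_template()] carrying a `"ground_truth"` attribute
#'   (list with `ttp_ms`, `ahp_slope_uv_per_ms`, `t_trough_ms`, `t_peak_ms`).
#' @examples
#' wf <- generate_waveform(waveform_params(trough_to_peak_ms = 0.6))
#' trough_to_peak_latency(wf)
#' @export
generate_waveform <- function(params, seed = NULL) {
  if (!inherits(params, "waveform_params")) {
    params <- do.call(waveform_params, as.list(params))
  }
  sh <- .calibrate_waveform(params$trough_to_peak_ms,
                            params$trough_amplitude_uv,
                            params$ahp_slope_uv_per_ms,
                            params$total_duration_ms)
  fs <- params$sampling_rate_hz
  n <- round(params$total_duration_ms / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  v <- .wf_eval(t_ms, sh)
  if (params$noise_sd_uv > 0) {
    v <- v + with_seed(seed, stats::rnorm(n, 0, params$noise_sd_uv))
  }
  wf <- waveform_template(v, fs)
  attr(wf, "ground_truth") <- list(
    ttp_ms = params$trough_to_peak_ms,
    ahp_slope_uv_per_ms = params$ahp_slope_uv_per_ms,
    t_trough_ms = sh$t_trough_ms,
    t_peak_ms = sh$t_peak_ms
  )
  wf
}
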