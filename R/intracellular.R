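# Current-clamp sweep analysis: spike detection, frequency-current (F-I)
# curves from current steps, and first-action-potential properties
# (threshold, amplitude, afterhyperpolarization, half-amplitude width).

#' Current-clamp sweep
#'
#' @param voltage_mv sampled membrane voltage in mV.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param injected_current_pa injected current of the step, in pA.
#' @param baseline_mv nominal holding potential (default -70 mV).
#' @param step_window_s optional `c(start, end)` of the current step in
#'   seconds; defaults to the full sweep.
#' @return An object of class `current_clamp_sweep`.
#' @export
current_clamp_sweep <- function(voltage_mv, sampling_rate_hz,
                                injected_current_pa,
                                baseline_mv = -70, step_window_s = NULL) {
  if (!is.numeric(voltage_mv) || length(voltage_mv) < 16L ||
      !all(is.finite(voltage_mv))) {
    dg_stop("`voltage_mv` must be a finite numeric vector (>= 16 samples)")
  }
  assert_scalar(sampling_rate_hz, "sampling_rate_hz", lower = 0,
                strict_lower = TRUE)
  assert_scalar(injected_current_pa, "injected_current_pa")
  dur <- length(voltage_mv) / sampling_rate_hz
  if (is.null(step_window_s)) step_window_s <- c(0, dur)
  if (length(step_window_s) != 2L || step_window_s[1] < 0 ||
      step_window_s[2] > dur + 1e-9 || diff(step_window_s) <= 0) {
    dg_stop("`step_window_s` must be an increasing pair within the sweep")
  }
  structure(list(voltage_mv = as.numeric(voltage_mv),
                 sampling_rate_hz = sampling_rate_hz,
                 injected_current_pa = injected_current_pa,
                 baseline_mv = baseline_mv,
                 step_window_s = as.numeric(step_window_s)),
            class = "current_clamp_sweep")
}

#' @export
print.current_clamp_sweep <- function(x, ...) {
  cat(sprintf("<current_clamp_sweep> %g pA, %d samples @ %g kHz\n",
              x$injected_current_pa, length(x$voltage_mv),
              x$sampling_rate_hz / 1000))
  invisible(x)
}

# Central-difference dV/dt in mV/ms.
.sweep_dvdt <- function(sweep) {
  v <- sweep$voltage_mv
  n <- length(v)
  dt_ms <- 1000 / sweep$sampling_rate_hz
  d <- numeric(n)
  d[1L] <- (v[2L] - v[1L]) / dt_ms
  d[n] <- (v[n] - v[n - 1L]) / dt_ms
  d[2L:(n - 1L)] <- (v[3L:n] - v[1L:(n - 2L)]) / (2 * dt_ms)
  d
}

#' Detect action potentials in a current-clamp sweep
#'
#' Spike onsets are upward crossings of a dV/dt criterion (default
#' 20 mV/ms) that are followed within 2 ms by a suprathreshold voltage
#' (above `v_floor_mv`, default -20 mV), with a refractory lockout
#' (default 1 ms) between accepted onsets.
#'
#' @param sweep a [current_clamp_sweep()].
#' @param dvdt_threshold_mv_per_ms onset criterion (default 20 mV/ms).
#' @param v_floor_mv confirmation voltage (default -20 mV).
#' @param lockout_ms refractory lockout between onsets (default 1 ms).
#' @return A data frame with columns `index` and `time_s` (possibly empty).
#' @export
detect_spikes_intracellular <- function(sweep,
                                        dvdt_threshold_mv_per_ms = 20,
                                        v_floor_mv = -20,
                                        lockout_ms = 1) {
  stopifnot(inherits(sweep, "current_clamp_sweep"))
  d <- .sweep_dvdt(sweep)
  v <- sweep$voltage_mv
  n <- length(v)
  fs <- sweep$sampling_rate_hz
  confirm_n <- max(1L, round(0.002 * fs))
  crossings <- which(d[-1L] >= dvdt_threshold_mv_per_ms &
                       d[-n] < dvdt_threshold_mv_per_ms) + 1L
  keep <- integer(0)
  last_t <- -Inf
  for (i in crossings) {
    t_i <- (i - 1) / fs
    if (t_i - last_t < lockout_ms / 1000) next
    hi <- min(n, i + confirm_n)
    if (max(v[i:hi]) > v_floor_mv) {
      keep <- c(keep, i)
      last_t <- t_i
    }
  }
  data.frame(index = keep, time_s = (keep - 1) / fs)
}

#' Frequency-current (F-I) curve from a set of sweeps
#'
#' Spike count divided by step duration for each sweep, ordered by
#' injected current.  Sweeps sharing a current are aggregated by the mean
#' with a warning.
#'
#' @param sweeps a `sweep_set` (from [generate_intracellular_sweeps()]) or
#'   a plain list of [current_clamp_sweep()] objects.
#' @param ... passed to [detect_spikes_intracellular()].
#' @return A data frame of class `fi_curve` with columns `current_pa`,
#'   `rate_hz`, `n_spikes`.
#' @export
fi_curve <- function(sweeps, ...) {
  if (inherits(sweeps, "sweep_set")) sweeps <- sweeps$sweeps
  if (!length(sweeps) || !all(vapply(sweeps, inherits, TRUE,
                                     "current_clamp_sweep"))) {
    dg_stop("`sweeps` must be current_clamp_sweep objects")
  }
  fs0 <- sweeps[[1]]$sampling_rate_hz
  if (!all(vapply(sweeps, function(s) s$sampling_rate_hz, 0) == fs0)) {
    dg_stop("all sweeps must share one sampling rate")
  }
  rows <- lapply(sweeps, function(s) {
    sp <- detect_spikes_intracellular(s, ...)
    win <- s$step_window_s
    in_step <- sp$time_s >= win[1] & sp$time_s <= win[2]
    data.frame(current_pa = s$injected_current_pa,
               n_spikes = sum(in_step),
               rate_hz = sum(in_step) / diff(win))
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$current_pa)) {
    warning("duplicate current values aggregated by mean", call. = FALSE)
    tab <- stats::aggregate(cbind(n_spikes, rate_hz) ~ current_pa, tab, mean)
  }
  tab <- tab[order(tab$current_pa), c("current_pa", "rate_hz", "n_spikes")]
  rownames(tab) <- NULL
  class(tab) <- c("fi_curve", "data.frame")
  tab
}

#' @export
plot.fi_curve <- function(x, ...) {
  plot(x$current_pa, x$rate_hz, type = "b", pch = 16,
       xlab = "injected current (pA)", ylab = "firing rate (Hz)", ...)
  invisible(x)
}

# Linear interpolation of the time (s) where v crosses `level` between
# samples i and i+1.
.cross_time <- function(v, i, level, fs) {
  frac <- (level - v[i]) / (v[i + 1L] - v[i])
  (i - 1 + frac) / fs
}

#' First-action-potential properties
#'
#' Computed on the first detected action potential of the sweep:
#' * `threshold_mv` -- voltage where dV/dt first crosses the detection
#'   criterion (sub-sample, linearly interpolated);
#' * `amplitude_mv` -- peak voltage minus threshold;
#' * `ahp_mv` -- threshold minus the voltage minimum within
#'   `ahp_window_ms` after the peak;
#' * `half_width_ms` -- time between the two crossings of
#'   threshold + amplitude/2 (threshold-referenced half amplitude),
#'   crossings linearly interpolated.
#'
#' @param sweep a [current_clamp_sweep()] containing at least one spike.
#' @param dvdt_threshold_mv_per_ms onset criterion (default 20 mV/ms).
#' @param ahp_window_ms post-peak search window for the AHP minimum
#'   (default 10 ms).
#' @param peak_window_ms post-onset search window for the peak (default 5).
#' @return A list of class `ap_properties` with the four fields above plus
#'   `peak_mv` and `onset_time_s`.
#' @export
ap_properties <- function(sweep, dvdt_threshold_mv_per_ms = 20,
                          ahp_window_ms = 10, peak_window_ms = 5) {
  stopifnot(inherits(sweep, "current_clamp_sweep"))
  sp <- detect_spikes_intracellular(sweep, dvdt_threshold_mv_per_ms)
  if (!nrow(sp)) dg_stop("no action potential in sweep", "dg_no_ap")
  v <- sweep$voltage_mv
  n <- length(v)
  fs <- sweep$sampling_rate_hz
  d <- .sweep_dvdt(sweep)
  i0 <- sp$index[1L]

  # threshold: interpolate the dV/dt crossing, then read the voltage there
  frac <- if (i0 > 1L && d[i0] != d[i0 - 1L]) {
    (dvdt_threshold_mv_per_ms - d[i0 - 1L]) / (d[i0] - d[i0 - 1L])
  } else 0
  thr <- if (i0 > 1L) v[i0 - 1L] + frac * (v[i0] - v[i0 - 1L]) else v[i0]

  hi <- min(n, i0 + round(peak_window_ms / 1000 * fs))
  i_pk <- i0 - 1L + which.max(v[i0:hi])
  peak <- v[i_pk]
  amplitude <- peak - thr
  if (amplitude <= 0) dg_stop("no action potential in sweep", "dg_no_ap")

  ahp_hi <- min(n, i_pk + round(ahp_window_ms / 1000 * fs))
  ahp <- thr - min(v[(i_pk + 1L):ahp_hi])

  level <- thr + amplitude / 2
  i_up <- NA_integer_
  for (i in max(i0 - round(0.002 * fs), 1L):(i_pk - 1L)) {
    if (v[i] < level && v[i + 1L] >= level) i_up <- i
  }
  i_dn <- NA_integer_
  for (i in i_pk:(n - 1L)) {
    if (v[i] >= level && v[i + 1L] < level) { i_dn <- i; break }
  }
  if (is.na(i_up) || is.na(i_dn)) {
    dg_stop("could not resolve half-amplitude crossings", "dg_no_ap")
  }
  hw_ms <- 1000 * (.cross_time(v, i_dn, level, fs) -
                     .cross_time(v, i_up, level, fs))

  structure(list(threshold_mv = thr, amplitude_mv = amplitude,
                 ahp_mv = ahp, half_width_ms = hw_ms, peak_mv = peak,
                 onset_time_s = sp$time_s[1L]),
            class = "ap_properties")
}

#' @export
print.ap_properties <- function(x, ...) {
  cat(sprintf(
    "<ap_properties> threshold %.1f mV | amplitude %.1f mV | AHP %.1f mV | half-width %.3f ms\n",
    x$threshold_mv, x$amplitude_mv, x$ahp_mv, x$half_width_ms))
  invisible(x)
}
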