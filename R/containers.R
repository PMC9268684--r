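# Core data containers: mean spike waveform and sorted spike train.

#' Mean extracellular spike waveform
#'
#' Container for one unit's mean spike waveform, a regularly sampled voltage
#' series in microvolts. By extracellular convention the spike is
#' negative-going: the trough is the global minimum and is followed by a
#' positive-going peak.
#'
#' @param samples numeric vector of amplitudes in uV (at least 16 finite
#'   samples).
#' @param sampling_rate_hz sampling rate in Hz (default 20000, i.e. one
#'   sample every 0.05 ms).
#' @return An object of class `waveform_template`.
#' @examples
#' t_ms <- seq(0, 3, by = 0.05)
#' wf <- waveform_template(-100 * exp(-(t_ms - 1)^2 / 0.02) +
#'                          30 * exp(-(t_ms - 1.5)^2 / 0.08))
#' print(wf)
#' @export
waveform_template <- function(samples, sampling_rate_hz = 20000) {
  if (!is.numeric(samples) || length(samples) < 16L) {
    dg_stop("`samples` must be a numeric vector with at least 16 samples")
  }
  if (!all(is.finite(samples))) {
    dg_stop("waveform samples must all be finite")
  }
  assert_scalar(sampling_rate_hz, "sampling_rate_hz", lower = 0,
                strict_lower = TRUE)
  structure(
    list(samples = as.numeric(samples),
         sampling_rate_hz = as.numeric(sampling_rate_hz)),
    class = "waveform_template"
  )
}

#' @export
print.waveform_template <- function(x, ...) {
  dur_ms <- 1000 * length(x$samples) / x$sampling_rate_hz
  cat(sprintf(
    "<waveform_template> %d samples @ %g kHz (%.2f ms), range [%.1f, %.1f] uV\n",
    length(x$samples), x$sampling_rate_hz / 1000, dur_ms,
    min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
plot.waveform_template <- function(x, ...) {
  t_ms <- (seq_along(x$samples) - 1) / x$sampling_rate_hz * 1000
  plot(t_ms, x$samples, type = "l", xlab = "time (ms)",
       ylab = expression(paste("amplitude (", mu, "V)")), ...)
  invisible(x)
}

#' Sorted spike train
#'
#' Ordered spike times for one unit over a known recording span. Times are
#' strictly increasing and lie in `[0, duration_s]`.
#'
#' @param times_s numeric vector of spike times in seconds (may be empty).
#' @param duration_s recording duration in seconds (> 0).
#' @return An object of class `spike_train`.
#' @examples
#' st <- spike_train(c(0.1, 0.5, 0.9), duration_s = 10)
#' mean_firing_rate(st)
#' @export
spike_train <- function(times_s, duration_s) {
  assert_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (length(times_s) == 0L) times_s <- numeric(0)
  if (!is.numeric(times_s) || anyNA(times_s) || any(!is.finite(times_s))) {
    dg_stop("spike times must be finite numeric values")
  }
  times_s <- as.numeric(times_s)
  if (length(times_s) > 1L && any(diff(times_s) <= 0)) {
    dg_stop("spike times must be strictly increasing")
  }
  if (length(times_s) && (times_s[1L] < 0 || times_s[length(times_s)] > duration_s)) {
    dg_stop("spike times must lie within [0, duration_s]")
  }
  structure(list(times_s = times_s, duration_s = as.numeric(duration_s)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g s (%.3f Hz)\n",
              length(x$times_s), x$duration_s,
              length(x$times_s) / x$duration_s))
  invisible(x)
}
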