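# Per-unit discriminative features: trough-to-peak latency, ISI histogram
# and burst index, AHP metric from the waveform first derivative, and mean
# firing rate.

# Locate trough (global minimum) and the following positive-going peak.
# Inverted waveforms (global max before global min) are flipped with a
# warning unless `flip = FALSE`.  The peak is the first local maximum after
# the trough whose height above the trough is at least `prominence` of the
# post-trough range -- identical to the literal first local maximum on
# noiseless templates, robust to sample-level ripple otherwise.
.locate_extrema <- function(waveform, flip = TRUE, prominence = 0.05) {
  v <- waveform$samples
  n <- length(v)
  if (flip && which.max(v) < which.min(v)) {
    warning("waveform polarity looks inverted (max precedes min); flipping",
            call. = FALSE)
    v <- -v
  }
  i_tr <- which.min(v)
  if (i_tr <= 1L || i_tr >= n) {
    dg_stop("degenerate waveform: trough at the boundary",
            "dg_degenerate_waveform")
  }
  post <- v[(i_tr + 1L):n]
  rng <- max(post) - v[i_tr]
  if (rng <= 0) {
    dg_stop("degenerate waveform: no rise after the trough",
            "dg_degenerate_waveform")
  }
  i_pk <- NA_integer_
  for (i in (i_tr + 1L):(n - 1L)) {
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L] &&
        (v[i] - v[i_tr]) >= prominence * rng) {
      i_pk <- i
      break
    }
  }
  if (is.na(i_pk)) {
    dg_stop("degenerate waveform: no local maximum after the trough",
            "dg_degenerate_waveform")
  }
  list(v = v, i_trough = i_tr, i_peak = i_pk)
}

#' Trough-to-peak latency of a spike waveform
#'
#' Time from the waveform's global minimum (the extracellular trough) to
#' the first positive-going local maximum after it, in milliseconds.
#' Narrow-waveform units (latency at or below 0.4 ms) are putative
#' parvalbumin-expressing fast-spiking interneurons.
#'
#' @param waveform a [waveform_template()].
#' @param interpolate refine both extrema to sub-sample precision with a
#'   3-point parabolic fit (default `TRUE`).
#' @param flip auto-flip waveforms whose polarity looks inverted
#'   (default `TRUE`).
#' @return Latency in ms.
#' @export
trough_to_peak_latency <- function(waveform, interpolate = TRUE, flip = TRUE) {
  stopifnot(inherits(waveform, "waveform_template"))
  loc <- .locate_extrema(waveform, flip = flip)
  dt_ms <- 1000 / waveform$sampling_rate_hz
  off_tr <- 0
  off_pk <- 0
  if (interpolate) {
    v <- loc$v
    i <- loc$i_trough
    off_tr <- parabolic_vertex(v[i - 1L], v[i], v[i + 1L])
    j <- loc$i_peak
    if (j < length(v)) {
      off_pk <- parabolic_vertex(v[j - 1L], v[j], v[j + 1L])
    }
  }
  ((loc$i_peak + off_pk) - (loc$i_trough + off_tr)) * dt_ms
}

#' First derivative of a spike waveform
#'
#' Central differences scaled to uV/ms (one-sided at the boundaries); same
#' length as the input.
#'
#' @param waveform a [waveform_template()].
#' @return Numeric vector of dV/dt in uV/ms.
#' @export
first_derivative <- function(waveform) {
  stopifnot(inherits(waveform, "waveform_template"))
  v <- waveform$samples
  n <- length(v)
  dt_ms <- 1000 / waveform$sampling_rate_hz
  d <- numeric(n)
  d[1L] <- (v[2L] - v[1L]) / dt_ms
  d[n] <- (v[n] - v[n - 1L]) / dt_ms
  d[2L:(n - 1L)] <- (v[3L:n] - v[1L:(n - 2L)]) / (2 * dt_ms)
  d
}

#' Afterhyperpolarization metric from the waveform first derivative
#'
#' Maximum absolute value of the first derivative (uV/ms) inside the AHP
#' window.  The default window runs from just after the post-trough peak
#' to the end of the waveform (`mode = "post_peak_max"`); alternatives are
#' `"post_peak_min"` (magnitude of the most negative post-peak derivative)
#' and `"full_tail_max"` (window starts at the trough).  A bimodal split of
#' this metric around 70 uV/ms separates putative granule cells (large
#' values) from putative mossy cells (small values).
#'
#' @param waveform a [waveform_template()].
#' @param mode which extremum/window to report (see above).
#' @param refine refine the discrete maximum with a 3-point parabolic fit
#'   (default `TRUE`).
#' @param flip auto-flip inverted waveforms (default `TRUE`).
#' @return Nonnegative metric in uV/ms.
#' @export
ahp_derivative_metric <- function(waveform,
                                  mode = c("post_peak_max", "post_peak_min",
                                           "full_tail_max"),
                                  refine = TRUE, flip = TRUE) {
  stopifnot(inherits(waveform, "waveform_template"))
  mode <- match.arg(mode)
  loc <- .locate_extrema(waveform, flip = flip)
  wf <- waveform
  wf$samples <- loc$v  # polarity-corrected
  d <- first_derivative(wf)
  n <- length(d)
  start <- if (mode == "full_tail_max") loc$i_trough + 1L else loc$i_peak + 1L
  if (n - start + 1L < 3L) {
    dg_stop("degenerate waveform: AHP window shorter than 3 samples",
            "dg_degenerate_waveform")
  }
  win <- start:n
  target <- if (mode == "post_peak_min") -d[win] else abs(d[win])
  j <- win[which.max(target)]
  val <- if (mode == "post_peak_min") -d[j] else abs(d[j])
  if (refine && j > start && j < n) {
    y <- if (mode == "post_peak_min") -d else abs(d)
    val <- parabolic_peak_value(y[j - 1L], y[j], y[j + 1L])
  }
  max(val, 0)
}

#' Inter-spike-interval histogram
#'
#' Counts of successive-spike intervals in fixed-width bins covering at
#' least `[0, range_ms)`; intervals at or beyond the range are excluded,
#' not clipped.  Trains with fewer than two spikes give an all-zero
#' histogram.
#'
#' @param train a [spike_train()].
#' @param bin_width_ms bin width in ms (default 1).
#' @param range_ms upper edge of the histogram in ms (default 300).
#' @return A list of class `isi_histogram` with `breaks_ms` (bin edges),
#'   `counts`, `bin_width_ms` and `n_isi` (total ISI count including those
#'   beyond the range).
#' @export
isi_histogram <- function(train, bin_width_ms = 1, range_ms = 300) {
  stopifnot(inherits(train, "spike_train"))
  assert_scalar(bin_width_ms, "bin_width_ms", lower = 0, strict_lower = TRUE)
  assert_scalar(range_ms, "range_ms", lower = bin_width_ms)
  breaks <- seq(0, range_ms, by = bin_width_ms)
  if (breaks[length(breaks)] < range_ms) breaks <- c(breaks, range_ms)
  isis_ms <- diff(train$times_s) * 1000
  inside <- isis_ms[isis_ms < breaks[length(breaks)]]
  counts <- if (length(inside)) {
    tabulate(findInterval(inside, breaks, left.open = FALSE),
             nbins = length(breaks) - 1L)
  } else {
    integer(length(breaks) - 1L)
  }
  structure(list(breaks_ms = breaks, counts = counts,
                 bin_width_ms = bin_width_ms, n_isi = length(isis_ms)),
            class = "isi_histogram")
}

#' Burst index from the ISI distribution
#'
#' Ratio of the inter-spike-interval frequency in the 0-10 ms window to
#' that in the 200-300 ms window.  With the default `normalize =
#' "per_ms"`, each window count is divided by its width so the index is a
#' dimensionless ratio of per-ms frequencies; `"raw"` uses the raw count
#' ratio.  Values above 1.8 mark putative excitatory (bursting) units.
#'
#' Edge rules: an empty 0-10 ms window gives 0 regardless of the
#' denominator; an empty 200-300 ms window with a nonempty numerator gives
#' `Inf`, carrying a `"flags"` attribute `"infinite_bi"`.  Trains with
#' fewer than two spikes give 0 flagged `"few_spikes"`.
#'
#' @param train a [spike_train()].
#' @param normalize `"per_ms"` (default) or `"raw"`.
#' @return Nonnegative numeric (possibly `Inf`), with an optional
#'   `"flags"` character attribute.
#' @export
burst_index <- function(train, normalize = c("per_ms", "raw")) {
  stopifnot(inherits(train, "spike_train"))
  normalize <- match.arg(normalize)
  if (length(train$times_s) < 2L) {
    return(structure(0, flags = "few_spikes"))
  }
  h <- isi_histogram(train, bin_width_ms = 1, range_ms = 300)
  early <- sum(h$counts[1:10])     # [0, 10) ms
  late <- sum(h$counts[201:300])   # [200, 300) ms
  if (early == 0) return(0)
  if (late == 0) return(structure(Inf, flags = "infinite_bi"))
  if (normalize == "per_ms") (early / 10) / (late / 100) else early / late
}

#' Mean firing rate
#'
#' Spike count divided by recording duration, in Hz.
#'
#' @param train a [spike_train()].
#' @return Rate in Hz.
#' @export
mean_firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$times_s) / train$duration_s
}

#' Extract the full feature set for one unit
#'
#' Bundles trough-to-peak latency, burst index, AHP derivative metric and
#' mean firing rate.  Degenerate waveforms do not abort: the waveform
#' features are `NA` and the record carries a `"degenerate_waveform"` flag
#' so the classifier can mark the unit unclassifiable.
#'
#' @param waveform a [waveform_template()].
#' @param train a [spike_train()].
#' @param interpolate sub-sample refinement for the latency (default `TRUE`).
#' @param bi_normalize burst-index normalization (see [burst_index()]).
#' @param ahp_mode AHP window mode (see [ahp_derivative_metric()]).
#' @return A list of class `unit_features` with fields
#'   `trough_to_peak_ms`, `burst_index`, `ahp_uv_per_ms`,
#'   `firing_rate_hz` and `flags` (character vector, possibly empty).
#' @export
extract_features <- function(waveform, train, interpolate = TRUE,
                             bi_normalize = "per_ms",
                             ahp_mode = "post_peak_max") {
  flags <- character(0)
  ttp <- NA_real_
  ahp <- NA_real_
  ok <- tryCatch({
    ttp <- trough_to_peak_latency(waveform, interpolate = interpolate)
    ahp <- ahp_derivative_metric(waveform, mode = ahp_mode)
    TRUE
  }, dg_degenerate_waveform = function(e) FALSE)
  if (!ok) flags <- c(flags, "degenerate_waveform")
  bi <- burst_index(train, normalize = bi_normalize)
  flags <- c(flags, attr(bi, "flags"))
  rate <- mean_firing_rate(train)
  structure(
    list(trough_to_peak_ms = ttp,
         burst_index = as.numeric(bi),
         ahp_uv_per_ms = ahp,
         firing_rate_hz = rate,
         flags = flags),
    class = "unit_features"
  )
}

#' @export
print.unit_features <- function(x, ...) {
  cat(sprintf(
    "<unit_features> ttp %.3f ms | BI %.3g | AHP %.1f uV/ms | rate %.3f Hz%s\n",
    x$trough_to_peak_ms, x$burst_index, x$ahp_uv_per_ms, x$firing_rate_hz,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.unit_features <- function(x, ...) {
  data.frame(ttp_ms = x$trough_to_peak_ms, burst_index = x$burst_index,
             ahp_uv_per_ms = x$ahp_uv_per_ms, rate_hz = x$firing_rate_hz,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
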