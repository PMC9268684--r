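# Synthetic spike-train generator: Poisson, bursty and jittered-regular
# firing with an absolute refractory period enforced by thinning.

#' Parameters for a synthetic spike train
#'
#' @param mode firing mode: `"poisson"` (homogeneous Poisson with
#'   refractory thinning), `"bursty"` (Poisson burst onsets, geometric
#'   within-burst spike counts, short intra-burst intervals) or
#'   `"regular"` (jittered lattice at `1/rate_hz`).
#' @param rate_hz target firing rate in Hz. For `"bursty"` this is the
#'   overall target rate used to derive the burst-onset rate when
#'   `burst_onset_rate_hz` is `NULL`.
#' @param duration_s recording duration in seconds.
#' @param burst_onset_rate_hz rate of burst onsets (bursty mode only;
#'   default `rate_hz / spikes_per_burst_mean`).
#' @param intra_burst_isi_ms mean interval between spikes inside a burst
#'   (default 4 ms, well inside the 0-10 ms bursting window).
#' @param spikes_per_burst_mean mean spikes per burst (geometric; default 3).
#' @param refractory_ms absolute refractory period (default 1 ms);
#'   intervals shorter than this are removed by thinning.
#' @param jitter_frac standard deviation of regular-mode jitter as a
#'   fraction of the period (default 0.01).
#' @param seed integer seed; generation is a pure function of the
#'   parameters and this seed.
#' @return A validated list of class `train_params`.
#' @export
train_params <- function(mode = c("poisson", "bursty", "regular"),
                         rate_hz = 5,
                         duration_s = 300,
                         burst_onset_rate_hz = NULL,
                         intra_burst_isi_ms = 4,
                         spikes_per_burst_mean = 3,
                         refractory_ms = 1,
                         jitter_frac = 0.01,
                         seed = 1L) {
  mode <- match.arg(mode)
  assert_scalar(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  assert_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  assert_scalar(intra_burst_isi_ms, "intra_burst_isi_ms", lower = 0,
                strict_lower = TRUE)
  assert_scalar(spikes_per_burst_mean, "spikes_per_burst_mean", lower = 1)
  assert_scalar(refractory_ms, "refractory_ms", lower = 0, strict_lower = TRUE)
  assert_scalar(jitter_frac, "jitter_frac", lower = 0)
  if (is.null(burst_onset_rate_hz)) {
    burst_onset_rate_hz <- rate_hz / spikes_per_burst_mean
  }
  assert_scalar(burst_onset_rate_hz, "burst_onset_rate_hz", lower = 0,
                strict_lower = TRUE)
  structure(
    list(mode = mode, rate_hz = rate_hz, duration_s = duration_s,
         burst_onset_rate_hz = burst_onset_rate_hz,
         intra_burst_isi_ms = intra_burst_isi_ms,
         spikes_per_burst_mean = spikes_per_burst_mean,
         refractory_ms = refractory_ms, jitter_frac = jitter_frac,
         seed = as.integer(seed)),
    class = "train_params"
  )
}

# Remove spikes closer than the refractory period to the previously kept
# spike (thinning: preserves the mean rate to first order).
.apply_refractory <- function(times_s, refractory_s) {
  if (length(times_s) < 2L) return(times_s)
  if (min(diff(times_s)) >= refractory_s) return(times_s)  # fast path
  keep <- logical(length(times_s))
  keep[1L] <- TRUE
  last <- times_s[1L]
  for (i in 2L:length(times_s)) {
    if (times_s[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- times_s[i]
    }
  }
  times_s[keep]
}

#' Generate a synthetic spike train
#'
#' Deterministic given its parameters (which carry the seed). Spike times
#' are strictly increasing, lie in `[0, duration_s]`, and all inter-spike
#' intervals respect the refractory period.
#'
#' @param params a [train_params()] object.
#' @return A [spike_train()].
#' @examples
#' st <- generate_spike_train(train_params("bursty", rate_hz = 6,
#'                                         duration_s = 120, seed = 7))
#' burst_index(st)
#' @export
generate_spike_train <- function(params) {
  if (!inherits(params, "train_params")) {
    params <- do.call(train_params, as.list(params))
  }
  p <- params
  times <- with_seed(p$seed, {
    switch(p$mode,
      poisson = {
        n_exp <- stats::qpois(1 - 1e-9, p$rate_hz * p$duration_s) + 10
        isis <- stats::rexp(n_exp, rate = p$rate_hz)
        tt <- cumsum(isis)
        tt[tt <= p$duration_s]
      },
      bursty = {
        n_b <- stats::qpois(1 - 1e-9, p$burst_onset_rate_hz * p$duration_s) + 10
        onsets <- cumsum(stats::rexp(n_b, rate = p$burst_onset_rate_hz))
        onsets <- onsets[onsets <= p$duration_s]
        counts <- 1L + stats::rgeom(length(onsets),
                                    prob = 1 / p$spikes_per_burst_mean)
        tt <- unlist(lapply(seq_along(onsets), function(i) {
          k <- counts[i]
          # intra-burst intervals jittered +/-20% around the nominal value,
          # staying well inside the 0-10 ms window at the default 4 ms
          isis_ms <- p$intra_burst_isi_ms *
            stats::runif(k - 1L, min = 0.8, max = 1.2)
          onsets[i] + c(0, cumsum(isis_ms)) / 1000
        }), use.names = FALSE)
        sort(tt[tt <= p$duration_s])
      },
      regular = {
        period <- 1 / p$rate_hz
        lattice <- seq(period / 2, p$duration_s, by = period)
        tt <- lattice + stats::rnorm(length(lattice),
                                     sd = p$jitter_frac * period)
        tt <- sort(tt)
        tt[tt >= 0 & tt <= p$duration_s]
      }
    )
  })
  times <- times[times >= 0 & times <= p$duration_s]
  times <- .apply_refractory(unique(times), p$refractory_ms / 1000)
  spike_train(times, p$duration_s)
}
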