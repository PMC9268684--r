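# Three-stage putative cell-type classification:
#   1. trough-to-peak latency <= 0.4 ms      -> putative PV interneuron
#   2. burst index > 1.8                     -> putative excitatory, split by
#   3. AHP derivative metric vs 70 uV/ms     -> mossy (<) / granule (>=)
#   otherwise                                -> wide-waveform interneuron
# plus data-driven recovery of the AHP split point from its bimodal
# distribution.

#' Classifier configuration
#'
#' @param ttp_threshold_ms narrow/wide latency boundary (default 0.4 ms;
#'   latency at or below the boundary is narrow).
#' @param bi_threshold burst-index boundary (default 1.8; only values
#'   strictly above are excitatory).
#' @param ahp_threshold_uv_per_ms mossy/granule AHP boundary (default 70;
#'   values at or above go to granule -- documented tie rule).
#' @param precedence `"latency_first"` (default): a narrow *and* bursting
#'   unit is putative PV; `"bi_first"`: it is excitatory.
#' @param ahp_threshold_mode `"fixed"` (default) or `"data_driven"`
#'   (recover the boundary from the bimodal AHP distribution via
#'   [detect_bimodal_threshold()], falling back to the fixed value when no
#'   bimodality is found).
#' @return A validated list of class `classifier_config`.
#' @export
classifier_config <- function(ttp_threshold_ms = 0.4,
                              bi_threshold = 1.8,
                              ahp_threshold_uv_per_ms = 70,
                              precedence = c("latency_first", "bi_first"),
                              ahp_threshold_mode = c("fixed", "data_driven")) {
  assert_scalar(ttp_threshold_ms, "ttp_threshold_ms", lower = 0,
                strict_lower = TRUE)
  assert_scalar(bi_threshold, "bi_threshold", lower = 0, strict_lower = TRUE)
  assert_scalar(ahp_threshold_uv_per_ms, "ahp_threshold_uv_per_ms",
                lower = 0, strict_lower = TRUE)
  structure(
    list(ttp_threshold_ms = ttp_threshold_ms,
         bi_threshold = bi_threshold,
         ahp_threshold_uv_per_ms = ahp_threshold_uv_per_ms,
         precedence = match.arg(precedence),
         ahp_threshold_mode = match.arg(ahp_threshold_mode)),
    class = "classifier_config"
  )
}

#' Cell-type labels
#' @return The five possible labels.
#' @export
cell_class_labels <- function() {
  c("putative_PV", "wide_interneuron", "putative_mossy",
    "putative_granule", "unclassifiable")
}

#' Classify one unit
#'
#' Applies the three-stage threshold rules.  Burst index exactly at the
#' boundary is *not* excitatory ("higher than 1.8"); AHP exactly at the
#' boundary goes to granule.  Units flagged with a degenerate waveform are
#' `"unclassifiable"`.  A missing (`NA`) feature without a corresponding
#' quality flag is a contract violation and raises an error.
#'
#' @param features a [extract_features()] result, or any list with
#'   `trough_to_peak_ms`, `burst_index`, `ahp_uv_per_ms` and optional
#'   `flags`.
#' @param config a [classifier_config()].
#' @return One of [cell_class_labels()].
#' @examples
#' f <- list(trough_to_peak_ms = 0.6, burst_index = 2.5, ahp_uv_per_ms = 50)
#' classify_unit(f)  # "putative_mossy"
#' @export
classify_unit <- function(features, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  flags <- features$flags %||% character(0)
  if (any(c("degenerate_waveform", "missing_waveform") %in% flags)) {
    return("unclassifiable")
  }
  ttp <- features$trough_to_peak_ms
  bi <- features$burst_index
  ahp <- features$ahp_uv_per_ms
  if (is.null(ttp) || is.na(ttp) || is.null(bi) || is.na(bi)) {
    dg_stop("missing feature without a quality flag", "dg_contract_error")
  }
  narrow <- ttp <= config$ttp_threshold_ms
  bursting <- bi > config$bi_threshold
  split_excitatory <- function() {
    if (is.null(ahp) || is.na(ahp)) {
      dg_stop("missing AHP metric without a quality flag",
              "dg_contract_error")
    }
    if (ahp < config$ahp_threshold_uv_per_ms) "putative_mossy"
    else "putative_granule"
  }
  if (config$precedence == "latency_first") {
    if (narrow) return("putative_PV")
    if (bursting) return(split_excitatory())
    "wide_interneuron"
  } else {
    if (bursting) return(split_excitatory())
    if (narrow) return("putative_PV")
    "wide_interneuron"
  }
}

#' Recover the split point of a bimodal distribution
#'
#' Kernel density estimate (Sheather-Jones plug-in bandwidth) of the
#' values; the threshold is the density minimum between the two highest
#' modes.  Bimodality is asserted first: at least two modes with height at
#' least 5% of the tallest, and a valley at most 80% as high as the lower
#' of the two modes -- otherwise a no-bimodality error is raised (callers
#' fall back to the fixed threshold).
#'
#' @param values numeric vector (at least 20 values).
#' @param bw bandwidth rule passed to [stats::density()] (default `"SJ"`,
#'   with an automatic fallback to `"nrd0"` if it fails).
#' @param min_mode_frac minimum relative mode height (default 0.05).
#' @param max_valley_frac maximum valley/mode height ratio (default 0.8).
#' @return The threshold (a scalar), with attributes `modes` (x positions
#'   of the two modes used) and `valley_density`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 40, 5), rnorm(300, 100, 5))
#' detect_bimodal_threshold(x)  # ~70
#' @export
detect_bimodal_threshold <- function(values, bw = "SJ",
                                     min_mode_frac = 0.05,
                                     max_valley_frac = 0.8) {
  values <- values[is.finite(values)]
  if (length(values) < 20L) {
    dg_stop("need at least 20 values to assess bimodality")
  }
  dens <- tryCatch(stats::density(values, bw = bw, n = 1024),
                   error = function(e) stats::density(values, bw = "nrd0",
                                                      n = 1024))
  y <- dens$y
  x <- dens$x
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  modes <- which(is_max)
  modes <- modes[y[modes] >= min_mode_frac * max(y)]
  if (length(modes) < 2L) {
    dg_stop("distribution is not bimodal", "dg_no_bimodality")
  }
  top2 <- modes[order(y[modes], decreasing = TRUE)[1:2]]
  top2 <- sort(top2)
  between <- top2[1]:top2[2]
  i_val <- between[which.min(y[between])]
  if (y[i_val] > max_valley_frac * min(y[top2])) {
    dg_stop("distribution is not bimodal (no clear valley)",
            "dg_no_bimodality")
  }
  structure(x[i_val], modes = x[top2], valley_density = y[i_val])
}

#' Classify a cohort of units
#'
#' Applies [classify_unit()] to every row of a unit-features table.  With
#' `ahp_threshold_mode = "data_driven"` the AHP boundary is first
#' recovered from the AHP metrics of the excitatory candidates (units that
#' reach the AHP stage under the configured precedence); if no bimodality
#' is detected the fixed threshold is used with a warning.
#'
#' @param features a data frame with columns `unit_id`, `ttp_ms`,
#'   `burst_index`, `ahp_uv_per_ms` and optionally `flags`
#'   (semicolon-separated), e.g. from [compute_unit_features()].
#' @param config a [classifier_config()].
#' @return An object of class `dg_classification`: `units` (the input
#'   plus a `class` column), `counts` (named counts over all five labels),
#'   `threshold_used` (the AHP boundary actually applied) and `config`.
#' @export
classify_cohort <- function(features, config = classifier_config()) {
  if (!is.data.frame(features) || !nrow(features)) {
    dg_stop("`features` must be a nonempty data frame")
  }
  need <- c("unit_id", "ttp_ms", "burst_index", "ahp_uv_per_ms")
  if (!all(need %in% names(features))) {
    dg_stop(sprintf("feature table must have columns: %s",
                    paste(need, collapse = ", ")))
  }
  if (is.null(features$flags)) features$flags <- ""

  threshold_used <- config$ahp_threshold_uv_per_ms
  if (config$ahp_threshold_mode == "data_driven") {
    cand <- features$burst_index > config$bi_threshold &
      !is.na(features$ttp_ms)
    if (config$precedence == "latency_first") {
      cand <- cand & features$ttp_ms > config$ttp_threshold_ms
    }
    vals <- features$ahp_uv_per_ms[cand & !is.na(features$ahp_uv_per_ms)]
    threshold_used <- tryCatch(
      as.numeric(detect_bimodal_threshold(vals)),
      dg_error = function(e) {
        warning("data-driven AHP threshold unavailable (",
                conditionMessage(e), "); using fixed ",
                config$ahp_threshold_uv_per_ms, call. = FALSE)
        config$ahp_threshold_uv_per_ms
      })
  }
  cfg_used <- config
  cfg_used$ahp_threshold_uv_per_ms <- threshold_used

  labels <- vapply(seq_len(nrow(features)), function(i) {
    classify_unit(
      list(trough_to_peak_ms = features$ttp_ms[i],
           burst_index = features$burst_index[i],
           ahp_uv_per_ms = features$ahp_uv_per_ms[i],
           flags = strsplit(features$flags[i], ";", fixed = TRUE)[[1]]),
      cfg_used)
  }, character(1))

  units <- features
  units$class <- labels
  counts <- table(factor(labels, levels = cell_class_labels()))
  structure(list(units = units,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 threshold_used = threshold_used,
                 config = config),
            class = "dg_classification")
}

#' @export
print.dg_classification <- function(x, ...) {
  cat(sprintf("<dg_classification> %d units (AHP threshold %.1f uV/ms)\n",
              nrow(x$units), x$threshold_used))
  print(x$counts)
  invisible(x)
}

#' @export
summary.dg_classification <- function(object, ...) {
  cat(sprintf("Classification of %d units\n", nrow(object$units)))
  cat(sprintf("  latency boundary : %.2f ms\n", object$config$ttp_threshold_ms))
  cat(sprintf("  burst boundary   : %.2f\n", object$config$bi_threshold))
  cat(sprintf("  AHP boundary     : %.1f uV/ms (%s)\n",
              object$threshold_used, object$config$ahp_threshold_mode))
  print(object$counts)
  invisible(object)
}

#' @export
plot.dg_classification <- function(x, ...) {
  u <- x$units
  bi <- pmin(u$burst_index, 10)  # compress the axis; Inf plotted at cap
  cls <- factor(u$class, levels = cell_class_labels())
  plot(u$ttp_ms, bi, col = as.integer(cls), pch = 16,
       xlab = "trough-to-peak latency (ms)", ylab = "burst index (capped at 10)",
       ...)
  graphics::abline(v = x$config$ttp_threshold_ms, lty = 2)
  graphics::abline(h = x$config$bi_threshold, lty = 2)
  graphics::legend("topright", legend = levels(cls), col = seq_along(levels(cls)),
                   pch = 16, cex = 0.8)
  invisible(x)
}
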