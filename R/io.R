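# Plain-text unit-dataset IO.  Schemas (documented in inst/FORMATS.md):
#   spikes.csv    unit_id, time_s
#   waveforms.csv unit_id, s0 ... s{N-1}   (uV; sampling rate in a JSON
#                 sidecar next to the file, field sampling_rate_hz)
#   metadata.csv  unit_id, animal_id, group [, duration_s]
# Times are serialized in seconds and waveforms in uV with six decimals.

.fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "f")
}

#' Write a unit dataset to a directory
#'
#' Writes `spikes.csv`, `waveforms.csv` (+ `waveforms.json` sidecar with
#' the sampling rate), `metadata.csv` and, when ground truth is attached,
#' `ground_truth.csv` -- the same CSV dialects [read_units()] consumes.
#'
#' @param units a `dg_units` dataset (e.g. from [generate_cohort()]).
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_units <- function(units, dir) {
  stopifnot(inherits(units, "dg_units"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spikes <- do.call(rbind, lapply(names(units$trains), function(id) {
    tt <- units$trains[[id]]$times_s
    if (!length(tt)) return(NULL)
    data.frame(unit_id = id, time_s = .fmt_num(tt),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(spikes, file.path(dir, "spikes.csv"),
                   row.names = FALSE, quote = FALSE)
  if (length(units$waveforms)) {
    wmat <- t(vapply(units$waveforms, function(w) w$samples,
                     numeric(length(units$waveforms[[1]]$samples))))
    wdf <- data.frame(unit_id = names(units$waveforms),
                      matrix(.fmt_num(wmat), nrow = nrow(wmat)),
                      stringsAsFactors = FALSE)
    names(wdf) <- c("unit_id", sprintf("s%d", seq_len(ncol(wmat)) - 1L))
    utils::write.csv(wdf, file.path(dir, "waveforms.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(sampling_rate_hz = units$sampling_rate_hz),
                         file.path(dir, "waveforms.json"),
                         auto_unbox = TRUE)
  }
  utils::write.csv(units$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(units$truth)) {
    utils::write.csv(units$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

.read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) dg_stop(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   dg_stop(sprintf("malformed CSV %s: %s", path,
                                   conditionMessage(e)), "dg_parse_error")
                 })
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    dg_stop(sprintf("%s lacks required column(s): %s", path,
                    paste(missing, collapse = ", ")), "dg_parse_error")
  }
  df
}

#' Read a unit dataset from CSV files
#'
#' Joins long-format spike times, a wide waveform matrix and unit
#' metadata into a `dg_units` dataset.  Units missing any component are
#' flagged (never silently dropped); unit-id mismatches across files
#' raise a join warning with counts.
#'
#' @param spike_csv path to the spike-times CSV (`unit_id`, `time_s`).
#' @param waveform_csv path to the waveform CSV (`unit_id`, `s0`...),
#'   or `NULL` for a train-only dataset.
#' @param metadata_csv path to the metadata CSV (`unit_id`, `animal_id`,
#'   `group`, optional `duration_s`).
#' @param sampling_rate_hz waveform sampling rate; when `NULL`, read from
#'   the JSON sidecar next to `waveform_csv` (default 20000 if absent).
#' @return A `dg_units` object (see [generate_cohort()]).
#' @export
read_units <- function(spike_csv, waveform_csv = NULL, metadata_csv,
                       sampling_rate_hz = NULL) {
  spikes <- .read_csv_checked(spike_csv, c("unit_id", "time_s"))
  if (anyNA(suppressWarnings(as.numeric(spikes$time_s)))) {
    bad <- which(is.na(suppressWarnings(as.numeric(spikes$time_s))))[1L]
    dg_stop(sprintf("non-numeric spike time at %s line %d", spike_csv,
                    bad + 1L), "dg_parse_error")
  }
  spikes$time_s <- as.numeric(spikes$time_s)
  meta <- .read_csv_checked(metadata_csv, c("unit_id", "animal_id", "group"))

  waveforms <- list()
  fs <- sampling_rate_hz
  if (!is.null(waveform_csv)) {
    wdf <- .read_csv_checked(waveform_csv, "unit_id")
    scols <- grep("^s[0-9]+$", names(wdf), value = TRUE)
    if (length(scols) < 16L) {
      dg_stop(sprintf("%s has fewer than 16 sample columns", waveform_csv),
              "dg_parse_error")
    }
    if (is.null(fs)) {
      sidecar <- sub("\\.csv$", ".json", waveform_csv)
      fs <- if (file.exists(sidecar)) {
        jsonlite::read_json(sidecar)$sampling_rate_hz %||% 20000
      } else 20000
    }
    wm <- as.matrix(wdf[, scols])
    if (!is.numeric(wm) || anyNA(wm)) {
      bad <- which(apply(wdf[, scols], 1,
                         function(r) anyNA(suppressWarnings(as.numeric(r)))))[1L]
      dg_stop(sprintf("non-numeric or missing waveform sample in %s row %d",
                      waveform_csv, bad), "dg_parse_error")
    }
    for (i in seq_len(nrow(wdf))) {
      waveforms[[wdf$unit_id[i]]] <- waveform_template(wm[i, ], fs)
    }
  } else if (is.null(fs)) {
    fs <- 20000
  }

  ids <- unique(c(meta$unit_id, spikes$unit_id, names(waveforms)))
  flags <- character(0)
  in_meta <- ids %in% meta$unit_id
  in_spk <- ids %in% spikes$unit_id
  if (!all(in_meta & in_spk)) {
    warning(sprintf(
      "unit_id mismatch across files: %d units total, %d missing metadata, %d missing spikes",
      length(ids), sum(!in_meta), sum(!in_spk)), call. = FALSE)
  }

  trains <- list()
  for (id in ids) {
    tt <- sort(unique(spikes$time_s[spikes$unit_id == id]))
    dur <- NA_real_
    if ("duration_s" %in% names(meta) && id %in% meta$unit_id) {
      dur <- meta$duration_s[match(id, meta$unit_id)]
    }
    if (!is.finite(dur)) {
      dur <- if (length(tt)) max(tt) else 1
      flags[id] <- paste(c(flags[id][!is.na(flags[id])],
                           "duration_inferred"), collapse = ";")
    }
    trains[[id]] <- spike_train(tt, dur)
    if (!(id %in% meta$unit_id)) {
      flags[id] <- paste(c(flags[id][!is.na(flags[id])], "missing_metadata"),
                         collapse = ";")
    }
    if (!(id %in% spikes$unit_id)) {
      flags[id] <- paste(c(flags[id][!is.na(flags[id])], "missing_spikes"),
                         collapse = ";")
    }
    if (length(waveforms) && !(id %in% names(waveforms))) {
      flags[id] <- paste(c(flags[id][!is.na(flags[id])], "missing_waveform"),
                         collapse = ";")
    }
  }
  meta_full <- merge(data.frame(unit_id = ids, stringsAsFactors = FALSE),
                     meta, by = "unit_id", all.x = TRUE, sort = FALSE)
  meta_full <- meta_full[match(ids, meta_full$unit_id), ]
  rownames(meta_full) <- NULL
  structure(list(waveforms = waveforms, trains = trains,
                 metadata = meta_full, sampling_rate_hz = fs,
                 flags = flags, truth = NULL),
            class = "dg_units")
}

#' Compute the feature table of a unit dataset
#'
#' Runs [extract_features()] on every unit, returning one row per unit.
#' Units without a waveform get `NA` waveform features and a
#' `missing_waveform` flag; degenerate waveforms are flagged, not fatal.
#'
#' @param units a `dg_units` dataset.
#' @param ... passed to [extract_features()].
#' @return A data frame with columns `unit_id`, `ttp_ms`, `burst_index`,
#'   `ahp_uv_per_ms`, `rate_hz`, `flags`.
#' @export
compute_unit_features <- function(units, ...) {
  stopifnot(inherits(units, "dg_units"))
  ids <- units$metadata$unit_id
  rows <- lapply(ids, function(id) {
    tr <- units$trains[[id]]
    wf <- units$waveforms[[id]]
    pre_flags <- units$flags[id]
    pre_flags <- if (is.na(pre_flags)) character(0) else
      strsplit(pre_flags, ";", fixed = TRUE)[[1]]
    if (is.null(wf)) {
      bi <- burst_index(tr)
      f <- data.frame(ttp_ms = NA_real_, burst_index = as.numeric(bi),
                      ahp_uv_per_ms = NA_real_,
                      rate_hz = mean_firing_rate(tr),
                      flags = paste(unique(c(pre_flags, "missing_waveform",
                                             attr(bi, "flags"))),
                                    collapse = ";"),
                      stringsAsFactors = FALSE)
    } else {
      f <- as.data.frame(extract_features(wf, tr, ...))
      f$flags <- paste(unique(c(pre_flags,
                                strsplit(f$flags, ";")[[1]])), collapse = ";")
    }
    cbind(data.frame(unit_id = id, stringsAsFactors = FALSE), f)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
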