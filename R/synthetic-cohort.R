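# Ground-truthed synthetic cohorts: four unit classes x experimental
# groups, with class-specific waveform/firing parameters and group-wise
# rate multipliers emulating the chronic-social-defeat effect directions
# (PV rate elevated only in susceptible animals; granule-cell rate reduced
# in susceptible animals and restored by ketamine; mossy and
# wide-interneuron rates equal across non-defeated/resilient/susceptible).

.default_class_params <- function() {
  list(
    putative_PV = list(
      ttp_ms = 0.25, ttp_sd = 0.03, ahp = 100, ahp_sd = 8,
      rate_hz = 15, mode = "regular"),
    wide_interneuron = list(
      ttp_ms = 0.60, ttp_sd = 0.05, ahp = 90, ahp_sd = 8,
      rate_hz = 8, mode = "regular"),
    putative_mossy = list(
      ttp_ms = 0.60, ttp_sd = 0.05, ahp = 40, ahp_sd = 5,
      rate_hz = 4, mode = "bursty"),
    putative_granule = list(
      ttp_ms = 0.70, ttp_sd = 0.05, ahp = 100, ahp_sd = 5,
      rate_hz = 1.5, mode = "bursty")
  )
}

.default_multipliers <- function() {
  groups <- c("ND", "Res", "Sus", "Sus+Ket")
  m <- matrix(1, nrow = 4, ncol = 4,
              dimnames = list(names(.default_class_params()), groups))
  m["putative_PV", "Sus"] <- 1.5        # PV rate elevated only in Sus
  m["putative_granule", "Sus"] <- 0.5   # GC rate reduced in Sus
  m["putative_granule", "Sus+Ket"] <- 1.0
  m["putative_mossy", "Sus+Ket"] <- 1.5 # ketamine elevates MC rate
  m
}

#' Specification of a synthetic cohort
#'
#' @param groups experimental group labels (default the four-arm design
#'   `ND`, `Res`, `Sus`, `Sus+Ket`).
#' @param animals_per_group animals per group (default 5).
#' @param units_per_class_per_animal units of each class recorded per
#'   animal (default 2, i.e. 10 units per class per group).
#' @param class_params named list of per-class parameter lists (fields
#'   `ttp_ms`, `ttp_sd`, `ahp`, `ahp_sd`, `rate_hz`, `mode`); defaults give
#'   four well-separated classes relative to the 0.4 ms / 1.8 / 70 uV/ms
#'   decision boundaries.
#' @param group_rate_multipliers class x group matrix of positive rate
#'   factors; the default encodes the defeat/ketamine effect directions.
#' @param duration_s recording duration per unit (default 300 s).
#' @param rate_sdlog unit-level log-normal spread of firing rates
#'   (default 0.4).
#' @param animal_sdlog animal-level log-normal rate effect (default 0.1).
#' @param noise_sd_uv waveform noise (default 0.2 uV: a mean waveform
#'   averaged over thousands of spikes is nearly noise-free, and the
#'   derivative-based AHP metric amplifies sample-level noise).
#' @param trough_amplitude_uv waveform trough amplitude (default -150).
#' @param include_waveforms generate waveforms (`TRUE`, default) or only
#'   spike trains and ground truth (`FALSE`, cheap rate-only cohorts for
#'   statistical simulations).
#' @param seed integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c("ND", "Res", "Sus", "Sus+Ket"),
                        animals_per_group = 5,
                        units_per_class_per_animal = 2,
                        class_params = .default_class_params(),
                        group_rate_multipliers = NULL,
                        duration_s = 300,
                        rate_sdlog = 0.4,
                        animal_sdlog = 0.1,
                        noise_sd_uv = 0.2,
                        trough_amplitude_uv = -150,
                        include_waveforms = TRUE,
                        seed = 1L) {
  if (length(groups) < 1L || anyDuplicated(groups)) {
    dg_stop("`groups` must be a nonempty set of unique labels")
  }
  assert_scalar(animals_per_group, "animals_per_group", lower = 1)
  assert_scalar(units_per_class_per_animal, "units_per_class_per_animal",
                lower = 1)
  if (!length(class_params) || is.null(names(class_params))) {
    dg_stop("`class_params` must be a named list with at least one class")
  }
  if (is.null(group_rate_multipliers)) {
    group_rate_multipliers <- .default_multipliers()
    group_rate_multipliers <- group_rate_multipliers[
      intersect(rownames(group_rate_multipliers), names(class_params)),
      intersect(colnames(group_rate_multipliers), groups), drop = FALSE]
  }
  m <- group_rate_multipliers
  if (!is.matrix(m) || !all(names(class_params) %in% rownames(m)) ||
      !all(groups %in% colnames(m)) || any(m <= 0)) {
    dg_stop("`group_rate_multipliers` must be a positive class x group matrix covering all classes and groups")
  }
  assert_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  assert_scalar(rate_sdlog, "rate_sdlog", lower = 0)
  assert_scalar(animal_sdlog, "animal_sdlog", lower = 0)
  assert_scalar(noise_sd_uv, "noise_sd_uv", lower = 0)
  structure(
    list(groups = groups,
         animals_per_group = as.integer(animals_per_group),
         units_per_class_per_animal = as.integer(units_per_class_per_animal),
         class_params = class_params,
         group_rate_multipliers = m,
         duration_s = duration_s,
         rate_sdlog = rate_sdlog,
         animal_sdlog = animal_sdlog,
         noise_sd_uv = noise_sd_uv,
         trough_amplitude_uv = trough_amplitude_uv,
         include_waveforms = isTRUE(include_waveforms),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a ground-truthed synthetic cohort
#'
#' Draws, for every animal and class, per-unit waveform and firing
#' parameters around the class means, applies the group rate multiplier,
#' and generates the mean waveform and spike train for each unit.  The
#' result is a `dg_units` dataset (the same container [read_units()]
#' produces) with a ground-truth table attached.
#'
#' @param spec a [cohort_spec()].
#' @return A `dg_units` object: named lists `waveforms` and `trains`,
#'   a `metadata` data frame (`unit_id`, `animal_id`, `group`,
#'   `duration_s`), `sampling_rate_hz`, `flags`, and a `truth` data frame
#'   (`unit_id`, `true_class`, `true_ttp_ms`, `true_rate_hz`,
#'   `true_ahp_slope_uv_per_ms`, `animal_id`, `group`).
#' @examples
#' units <- generate_cohort(cohort_spec(animals_per_group = 1, seed = 42))
#' nrow(units$metadata)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) {
    dg_stop("`spec` must be a cohort_spec object")
  }
  classes <- names(spec$class_params)
  n_units <- length(spec$groups) * spec$animals_per_group *
    length(classes) * spec$units_per_class_per_animal
  if (n_units < 1L) dg_stop("cohort spec yields zero units")

  draws <- with_seed(spec$seed, {
    out <- vector("list", n_units)
    k <- 0L
    for (g in spec$groups) {
      for (a in seq_len(spec$animals_per_group)) {
        animal_id <- sprintf("%s_a%02d", gsub("[^A-Za-z0-9]+", "", g), a)
        animal_eff <- stats::rlnorm(1, meanlog = -spec$animal_sdlog^2 / 2,
                                    sdlog = spec$animal_sdlog)
        for (cl in classes) {
          cp <- spec$class_params[[cl]]
          mult <- spec$group_rate_multipliers[cl, g]
          for (u in seq_len(spec$units_per_class_per_animal)) {
            k <- k + 1L
            ttp <- max(0.12, stats::rnorm(1, cp$ttp_ms, cp$ttp_sd))
            ahp <- max(15, stats::rnorm(1, cp$ahp, cp$ahp_sd))
            rate <- cp$rate_hz * mult * animal_eff *
              stats::rlnorm(1, meanlog = -spec$rate_sdlog^2 / 2,
                            sdlog = spec$rate_sdlog)
            rate <- max(rate, 2 / spec$duration_s)
            out[[k]] <- list(
              unit_id = sprintf("u%04d", k), animal_id = animal_id,
              group = g, class = cl, ttp = ttp, ahp = ahp, rate = rate,
              mode = cp$mode,
              seed_wf = spec$seed * 1000L + k,
              seed_tr = spec$seed * 1000L + 500000L + k)
          }
        }
      }
    }
    out
  })

  waveforms <- list()
  trains <- list()
  fs <- 20000
  for (d in draws) {
    if (spec$include_waveforms) {
      wp <- waveform_params(trough_to_peak_ms = d$ttp,
                            trough_amplitude_uv = spec$trough_amplitude_uv,
                            ahp_slope_uv_per_ms = d$ahp,
                            noise_sd_uv = spec$noise_sd_uv,
                            sampling_rate_hz = fs)
      waveforms[[d$unit_id]] <- generate_waveform(wp, seed = d$seed_wf)
    }
    tp <- train_params(mode = d$mode, rate_hz = d$rate,
                       duration_s = spec$duration_s, seed = d$seed_tr)
    trains[[d$unit_id]] <- generate_spike_train(tp)
  }

  metadata <- data.frame(
    unit_id = vapply(draws, `[[`, "", "unit_id"),
    animal_id = vapply(draws, `[[`, "", "animal_id"),
    group = vapply(draws, `[[`, "", "group"),
    duration_s = spec$duration_s,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    unit_id = metadata$unit_id,
    true_class = vapply(draws, `[[`, "", "class"),
    true_ttp_ms = vapply(draws, `[[`, 0, "ttp"),
    true_rate_hz = vapply(draws, `[[`, 0, "rate"),
    true_ahp_slope_uv_per_ms = vapply(draws, `[[`, 0, "ahp"),
    animal_id = metadata$animal_id,
    group = metadata$group,
    stringsAsFactors = FALSE
  )
  structure(
    list(waveforms = waveforms, trains = trains, metadata = metadata,
         sampling_rate_hz = fs, flags = character(0), truth = truth,
         spec = spec),
    class = "dg_units"
  )
}

#' @export
print.dg_units <- function(x, ...) {
  cat(sprintf("<dg_units> %d units (%d with waveforms), %d animals, groups: %s\n",
              nrow(x$metadata), length(x$waveforms),
              length(unique(x$metadata$animal_id)),
              paste(unique(x$metadata$group), collapse = ", ")))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}
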