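# Behavioral scoring for chronic social defeat: social-interaction (SI)
# ratio, susceptible/resilient phenotype, sucrose preference, and
# marker-vs-SI correlations.

#' Social interaction ratio
#'
#' Phase-2 (aggressor present) interaction-zone time divided by phase-1
#' (aggressor absent) time.  Defeated animals with a ratio below 1 are
#' susceptible; ratio at or above 1, resilient.
#'
#' @param phase1_s,phase2_s interaction-zone times in seconds (phase
#'   duration is 150 s each).
#' @return The SI ratio.
#' @export
si_ratio <- function(phase1_s, phase2_s) {
  assert_scalar(phase2_s, "phase2_s", lower = 0)
  if (!is.numeric(phase1_s) || length(phase1_s) != 1L ||
      !is.finite(phase1_s) || phase1_s <= 0) {
    dg_stop("SI ratio undefined: phase-1 interaction time is zero",
            "dg_undefined_ratio")
  }
  phase2_s / phase1_s
}

#' Assign a susceptible/resilient phenotype
#'
#' Defeated animals with SI ratio below 1 are `"susceptible"`; at or above
#' 1, `"resilient"` (the boundary ratio of exactly 1 counts as resilient).
#' Non-defeated animals get `"not_applicable"`.
#'
#' @param si_ratio the SI ratio (vectorized).
#' @param defeated logical, whether the animal underwent defeat.
#' @return Character vector of phenotypes.
#' @export
assign_phenotype <- function(si_ratio, defeated) {
  if (any(!is.finite(si_ratio) | si_ratio < 0)) {
    dg_stop("SI ratio must be a nonnegative finite value",
            "dg_undefined_ratio")
  }
  ifelse(!defeated, "not_applicable",
         ifelse(si_ratio < 1, "susceptible", "resilient"))
}

#' Sucrose preference
#'
#' `sucrose / (sucrose + water) * 100`, in percent.
#'
#' @param sucrose_ml,water_ml consumed volumes in mL (nonnegative).
#' @return Preference percentage in `[0, 100]`.
#' @export
sucrose_preference <- function(sucrose_ml, water_ml) {
  assert_scalar(sucrose_ml, "sucrose_ml", lower = 0)
  assert_scalar(water_ml, "water_ml", lower = 0)
  if (sucrose_ml + water_ml <= 0) {
    dg_stop("sucrose preference undefined: zero total consumption",
            "dg_undefined_preference")
  }
  100 * sucrose_ml / (sucrose_ml + water_ml)
}

#' Score a behavior table
#'
#' Adds `si_ratio`, `phenotype` and `sucrose_pref_pct` columns to a table
#' with columns `animal_id`, `group`, `defeated`, `phase1_s`, `phase2_s`
#' and optionally `sucrose_ml`, `water_ml`.  Rows with zero phase-1 time
#' get `NA` ratio and phenotype `"excluded"` (flagged, never silently
#' dropped); rows with zero total consumption get `NA` preference.
#'
#' @param behavior a behavior data frame (e.g. from [generate_behavior()]).
#' @return The input with the three scored columns appended.
#' @export
score_behavior <- function(behavior) {
  need <- c("animal_id", "group", "defeated", "phase1_s", "phase2_s")
  if (!is.data.frame(behavior) || !all(need %in% names(behavior))) {
    dg_stop(sprintf("behavior table must have columns: %s",
                    paste(need, collapse = ", ")))
  }
  ok <- is.finite(behavior$phase1_s) & behavior$phase1_s > 0
  si <- ifelse(ok, behavior$phase2_s / behavior$phase1_s, NA_real_)
  phen <- rep("excluded", nrow(behavior))
  phen[ok] <- assign_phenotype(si[ok], behavior$defeated[ok])
  behavior$si_ratio <- si
  behavior$phenotype <- phen
  if (all(c("sucrose_ml", "water_ml") %in% names(behavior))) {
    tot <- behavior$sucrose_ml + behavior$water_ml
    behavior$sucrose_pref_pct <- ifelse(tot > 0,
                                        100 * behavior$sucrose_ml / tot,
                                        NA_real_)
  }
  behavior
}

#' Correlate a molecular marker with the SI ratio
#'
#' Pearson product-moment correlation with a two-sided p-value; pairs with
#' missing values are dropped listwise and the effective n is reported.
#'
#' @param marker_values numeric marker levels (one per animal).
#' @param si_ratios matched SI ratios.
#' @return A list of class `dg_correlation` with `r`, `p_value`, `n`.
#' @examples
#' set.seed(1)
#' si <- rlnorm(30, 0, 0.3)
#' marker <- 2 - si + rnorm(30, 0, 0.3)
#' marker_behavior_correlation(marker, si)
#' @export
marker_behavior_correlation <- function(marker_values, si_ratios) {
  if (length(marker_values) != length(si_ratios)) {
    dg_stop("marker and SI series must have equal length")
  }
  keep <- is.finite(marker_values) & is.finite(si_ratios)
  x <- marker_values[keep]
  y <- si_ratios[keep]
  if (length(x) < 3L) dg_stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    dg_stop("correlation undefined: zero variance", "dg_degenerate_variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "dg_correlation")
}

#' @export
print.dg_correlation <- function(x, ...) {
  cat(sprintf("<pearson correlation> r = %.4f, p = %.4g, n = %d\n",
              x$r, x$p_value, x$n))
  invisible(x)
}
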