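# Group-level firing-rate workflow: per cell class, gate on normality,
# then route to one-way ANOVA/Bonferroni or Kruskal-Wallis/Dunn.

#' Compare firing rates across groups, per cell class
#'
#' For every cell class the firing rates are gated with the per-group
#' D'Agostino-Pearson test: if every group passes (p >= alpha) the class
#' is analyzed with a one-way ANOVA and Bonferroni post hoc comparisons,
#' otherwise (including any group too small for the normality test) with
#' Kruskal-Wallis and Dunn's post hoc.  Classes represented in fewer than
#' two groups (or with groups of fewer than two units) are skipped with a
#' warning.
#'
#' @param units a data frame with columns `class`, `group`, `rate_hz`
#'   (one row per unit), or a [classify_cohort()] result whose `units`
#'   table carries `group` and `rate_hz`.
#' @param alpha significance level (default 0.05).
#' @param classes optional subset of classes to analyze.
#' @return A tidy data frame (class `dg_group_stats`) with columns
#'   `class`, `comparison` (`"omnibus"` or `"<a> vs <b>"`), `test_name`,
#'   `statistic`, `p_value`, `p_adjusted`, `n`; the full `dg_comparison`
#'   objects are attached as the `"results"` attribute.
#' @export
compare_firing_by_group <- function(units, alpha = 0.05, classes = NULL) {
  if (inherits(units, "dg_classification")) units <- units$units
  need <- c("class", "group", "rate_hz")
  if (!is.data.frame(units) || !all(need %in% names(units))) {
    dg_stop(sprintf("`units` must have columns: %s",
                    paste(need, collapse = ", ")))
  }
  if (is.null(classes)) {
    classes <- setdiff(unique(units$class), "unclassifiable")
  }
  rows <- list()
  results <- list()
  for (cl in classes) {
    sub <- units[units$class == cl & is.finite(units$rate_hz), ]
    tab <- table(sub$group)
    tab <- tab[tab >= 2]
    if (length(tab) < 2L) {
      warning(sprintf("class %s represented in fewer than 2 groups; skipped",
                      cl), call. = FALSE)
      next
    }
    sub <- sub[sub$group %in% names(tab), ]
    gate <- tryCatch(normality_gate(sub$rate_hz, sub$group, alpha = alpha),
                     dg_small_sample = function(e) NULL)
    res <- if (!is.null(gate) && gate$pass) {
      one_way_anova_bonferroni(sub$rate_hz, sub$group, alpha = alpha)
    } else {
      kruskal_dunn(sub$rate_hz, sub$group, alpha = alpha)
    }
    res$normality_ps <- gate$p_values
    results[[cl]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, comparison = "omnibus", test_name = res$test_name,
      statistic = res$statistic, p_value = res$p_value,
      p_adjusted = res$p_value, n = nrow(sub), stringsAsFactors = FALSE)
    if (nrow(res$posthoc)) {
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, comparison = res$posthoc$comparison,
        test_name = res$test_name,
        statistic = if ("z" %in% names(res$posthoc)) res$posthoc$z else NA_real_,
        p_value = res$posthoc$p_raw,
        p_adjusted = res$posthoc$p_adjusted,
        n = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) dg_stop("no class could be analyzed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  class(out) <- c("dg_group_stats", "data.frame")
  out
}
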