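# Omnibus tests with multiple-comparison post hocs: one-way ANOVA with
# Bonferroni pairwise comparisons, Kruskal-Wallis with Dunn's post hoc,
# and two-way (type-II) ANOVA with optional subject blocking.

# Shared result container.
.comparison_result <- function(test_name, statistic, df, p_value, posthoc,
                               normality_ps = NULL, alpha = 0.05,
                               effects = NULL) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, posthoc = posthoc,
                 normality_ps = normality_ps, alpha = alpha,
                 effects = effects),
            class = "dg_comparison")
}

#' @export
print.dg_comparison <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  if (!is.null(x$effects)) {
    print(x$effects, row.names = FALSE)
  }
  if (!is.null(x$posthoc) && nrow(x$posthoc)) {
    cat("post hoc (Bonferroni-adjusted):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

.check_groups <- function(values, groups, min_per_group = 2L) {
  if (length(values) != length(groups)) {
    dg_stop("`values` and `groups` must have equal length")
  }
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) dg_stop("need at least 2 groups")
  if (any(table(groups) < min_per_group)) {
    dg_stop(sprintf("every group needs at least %d values", min_per_group))
  }
  list(values = values, groups = groups)
}

#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Omnibus F test followed by all pairwise t comparisons using the pooled
#' within-group variance; pairwise p-values are Bonferroni-adjusted (raw p
#' times the number of pairs, capped at 1).
#'
#' @param values numeric measurements.
#' @param groups parallel group labels (>= 2 groups, >= 2 values each).
#' @param alpha significance level recorded in the result (default 0.05).
#' @return A `dg_comparison` with the F `statistic`, `df` (c(between,
#'   within)), omnibus `p_value` and a `posthoc` data frame (`comparison`,
#'   `p_raw`, `p_adjusted`).
#' @export
one_way_anova_bonferroni <- function(values, groups, alpha = 0.05) {
  d <- .check_groups(values, groups)
  within_var <- tapply(d$values, d$groups, stats::var)
  if (all(within_var == 0)) {
    dg_stop("all groups have zero within-group variance",
            "dg_degenerate_variance")
  }
  fit <- stats::lm(d$values ~ d$groups)
  an <- stats::anova(fit)
  f_stat <- an$`F value`[1]
  p_omni <- an$`Pr(>F)`[1]
  df <- c(an$Df[1], an$Df[2])

  pt <- stats::pairwise.t.test(d$values, d$groups, pool.sd = TRUE,
                               p.adjust.method = "none")
  raw <- pt$p.value
  pairs <- which(!is.na(raw), arr.ind = TRUE)
  m <- nrow(pairs)
  posthoc <- data.frame(
    comparison = sprintf("%s vs %s", rownames(raw)[pairs[, 1]],
                         colnames(raw)[pairs[, 2]]),
    p_raw = raw[pairs],
    p_adjusted = pmin(1, raw[pairs] * m),
    stringsAsFactors = FALSE)
  .comparison_result("one_way_anova_bonferroni", f_stat, df, p_omni,
                     posthoc, alpha = alpha)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H followed by Dunn's pairwise z tests on
#' mean ranks (tie-corrected pooled variance), with Bonferroni adjustment
#' of the two-sided pairwise p-values.
#'
#' @inheritParams one_way_anova_bonferroni
#' @return A `dg_comparison` with the H `statistic`, omnibus `p_value`
#'   and a `posthoc` data frame (`comparison`, `z`, `p_raw`,
#'   `p_adjusted`).
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05) {
  d <- .check_groups(values, groups)
  if (length(unique(d$values)) == 1L) {
    dg_stop("all values identical: ranks are degenerate",
            "dg_degenerate_variance")
  }
  kw <- stats::kruskal.test(d$values, d$groups)

  r <- rank(d$values)
  n_tot <- length(r)
  mean_ranks <- tapply(r, d$groups, mean)
  n_g <- table(d$groups)
  ties <- table(d$values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  lev <- levels(d$groups)
  combos <- utils::combn(lev, 2)
  m <- ncol(combos)
  z <- numeric(m)
  for (k in seq_len(m)) {
    i <- combos[1, k]; j <- combos[2, k]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
                 (1 / n_g[[i]] + 1 / n_g[[j]]))
    z[k] <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
  }
  p_raw <- 2 * stats::pnorm(-abs(z))
  posthoc <- data.frame(
    comparison = sprintf("%s vs %s", combos[1, ], combos[2, ]),
    z = z, p_raw = p_raw, p_adjusted = pmin(1, p_raw * m),
    stringsAsFactors = FALSE)
  .comparison_result("kruskal_wallis_dunn", unname(kw$statistic),
                     unname(kw$parameter), kw$p.value, posthoc,
                     alpha = alpha)
}

#' Two-way ANOVA (type-II sums of squares)
#'
#' Main effects and interaction for two crossed factors, using type-II
#' sums of squares (each main effect adjusted for the other; robust
#' default for unbalanced designs, identical to type I when balanced).
#' An optional `subject` factor is included as an additive blocking term,
#' the standard approximation for repeated-measures designs (no
#' sphericity correction).  Post hoc: Bonferroni-adjusted pairwise t
#' comparisons of the factor-A levels within each level of factor B,
#' using the full-model residual variance.
#'
#' @param values numeric measurements.
#' @param factor_a,factor_b parallel factor labels (every crossed cell
#'   must be nonempty).
#' @param subject optional subject identifiers (blocking factor).
#' @param alpha significance level recorded in the result.
#' @return A `dg_comparison`; `effects` holds the ANOVA table (effect,
#'   df, sum_sq, F, p), `statistic`/`p_value` report the interaction, and
#'   `posthoc` the within-B pairwise comparisons of A.
#' @export
two_way_anova <- function(values, factor_a, factor_b, subject = NULL,
                          alpha = 0.05) {
  if (length(values) != length(factor_a) ||
      length(values) != length(factor_b)) {
    dg_stop("`values` and both factors must have equal length")
  }
  keep <- is.finite(values) & !is.na(factor_a) & !is.na(factor_b)
  dat <- data.frame(y = values[keep],
                    A = droplevels(factor(factor_a[keep])),
                    B = droplevels(factor(factor_b[keep])))
  if (nlevels(dat$A) < 2L || nlevels(dat$B) < 2L) {
    dg_stop("both factors need at least 2 levels")
  }
  cells <- table(dat$A, dat$B)
  if (any(cells == 0)) {
    dg_stop("empty design cell: every A x B combination needs data",
            "dg_design_error")
  }
  blocked <- !is.null(subject)
  if (blocked) dat$S <- droplevels(factor(subject[keep]))

  rss <- function(fml) sum(stats::resid(stats::lm(fml, data = dat))^2)
  base <- if (blocked) "S + " else ""
  full <- stats::lm(stats::as.formula(paste("y ~", base, "A * B")),
                    data = dat)
  rss_full <- sum(stats::resid(full)^2)
  df_res <- full$df.residual
  if (df_res < 1L || rss_full <= 0) {
    dg_stop("two-way ANOVA has no residual degrees of freedom",
            "dg_degenerate_variance")
  }
  mse <- rss_full / df_res

  rss_ab <- rss(stats::as.formula(paste("y ~", base, "A + B")))
  ss <- c(A = rss(stats::as.formula(paste("y ~", base, "B"))) - rss_ab,
          B = rss(stats::as.formula(paste("y ~", base, "A"))) - rss_ab,
          `A:B` = rss_ab - rss_full)
  dfs <- c(A = nlevels(dat$A) - 1L, B = nlevels(dat$B) - 1L,
           `A:B` = (nlevels(dat$A) - 1L) * (nlevels(dat$B) - 1L))
  f_vals <- (ss / dfs) / mse
  p_vals <- stats::pf(f_vals, dfs, df_res, lower.tail = FALSE)
  effects <- data.frame(effect = names(ss), df = as.integer(dfs),
                        sum_sq = unname(ss), F = unname(f_vals),
                        p = unname(p_vals), stringsAsFactors = FALSE)

  # post hoc: A-level pairs within each B level, pooled residual variance
  combos <- utils::combn(levels(dat$A), 2)
  rows <- list()
  for (b in levels(dat$B)) {
    for (k in seq_len(ncol(combos))) {
      a1 <- combos[1, k]; a2 <- combos[2, k]
      y1 <- dat$y[dat$A == a1 & dat$B == b]
      y2 <- dat$y[dat$A == a2 & dat$B == b]
      t_stat <- (mean(y1) - mean(y2)) /
        sqrt(mse * (1 / length(y1) + 1 / length(y2)))
      p <- 2 * stats::pt(-abs(t_stat), df_res)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = sprintf("%s vs %s | %s", a1, a2, b),
        t = t_stat, p_raw = p, stringsAsFactors = FALSE)
    }
  }
  posthoc <- do.call(rbind, rows)
  posthoc$p_adjusted <- pmin(1, posthoc$p_raw * nrow(posthoc))

  .comparison_result(if (blocked) "two_way_anova_rm" else "two_way_anova",
                     unname(f_vals["A:B"]), c(dfs[["A:B"]], df_res),
                     unname(p_vals["A:B"]), posthoc, alpha = alpha,
                     effects = effects)
}
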