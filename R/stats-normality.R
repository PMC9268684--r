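# D'Agostino-Pearson omnibus normality test and the per-group gate that
# routes measurements to the parametric or nonparametric branch.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and
#' transformed sample kurtosis (Anscombe & Glynn 1983) into the K-squared
#' statistic, chi-squared with 2 degrees of freedom under normality
#' (D'Agostino, Belanger & D'Agostino Jr 1990).
#'
#' @param x numeric sample (n >= 8; smaller samples raise a
#'   `dg_small_sample` error so callers can route to a nonparametric
#'   branch).
#' @return A list of class `dg_normality` with `statistic` (K-squared),
#'   `p_value`, `z_skewness`, `z_kurtosis`, `n`.
#' @examples
#' set.seed(1)
#' dagostino_pearson(rnorm(100))$p_value
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) {
    dg_stop("D'Agostino-Pearson test needs at least 8 observations",
            "dg_small_sample")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    dg_stop("normality test undefined: zero variance",
            "dg_degenerate_variance")
  }
  b1 <- mean((x - m)^3) / m2^1.5   # sample skewness (g1)
  b2 <- mean((x - m)^4) / m2^2     # sample kurtosis (g2 + 3)

  # skewness z (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_s <- delta * asinh(y / alpha)

  # kurtosis z (Anscombe & Glynn 1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  z_k <- ((1 - 2 / (9 * a)) -
            ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_s^2 + z_k^2
  structure(list(statistic = k2,
                 p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 z_skewness = z_s, z_kurtosis = z_k, n = n),
            class = "dg_normality")
}

#' @export
print.dg_normality <- function(x, ...) {
  cat(sprintf("<D'Agostino-Pearson> K2 = %.3f, p = %.4g (n = %d)\n",
              x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Per-group normality gate
#'
#' Runs [dagostino_pearson()] in every group; the gate passes (parametric
#' branch) only when every group's p-value is at or above `alpha`.  Any
#' group with fewer than 8 values raises a `dg_small_sample` error so the
#' caller can route directly to the nonparametric branch.
#'
#' @param values numeric measurements.
#' @param groups parallel group labels.
#' @param alpha significance level (default 0.05).
#' @return A list with `p_values` (named per group) and `pass` (logical).
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  if (length(values) != length(groups)) {
    dg_stop("`values` and `groups` must have equal length")
  }
  by_group <- split(values, groups)
  if (length(by_group) < 2L) dg_stop("need at least 2 groups")
  ps <- vapply(by_group, function(v) dagostino_pearson(v)$p_value, 0)
  list(p_values = ps, pass = all(ps >= alpha))
}
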