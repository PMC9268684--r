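# Internal helpers shared across modules.

#' Signal a classed package error
#'
#' All anticipated failure modes raise conditions inheriting from
#' `"dg_error"` plus a specific subclass (`"dg_param_error"`,
#' `"dg_degenerate_waveform"`, `"dg_no_bimodality"`, `"dg_no_ap"`,
#' `"dg_small_sample"`, `"dg_degenerate_variance"`, `"dg_undefined_ratio"`,
#' `"dg_config_error"`), so callers can route on the failure kind with
#' `tryCatch()`.
#'
#' @param message error message.
#' @param class specific condition class, prepended to `"dg_error"`.
#' @noRd
dg_stop <- function(message, class = "dg_param_error") {
  stop(structure(
    class = c(class, "dg_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores (or removes) `.Random.seed` afterwards so generators are pure
#' functions of their arguments and never disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Scalar validation: finite numeric of length 1 within (lower, upper).
assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    dg_stop(sprintf("`%s` must be a finite numeric scalar", name))
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    dg_stop(sprintf("`%s` = %g is outside its allowed range", name, x))
  }
  invisible(x)
}

# Sub-sample offset of the vertex of the parabola through three equally
# spaced points; clamped to half a sample either side.
parabolic_vertex <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < 1e-12 * max(abs(c(ym1, y0, yp1)), 1e-300)) {
    return(0)
  }
  off <- 0.5 * (ym1 - yp1) / denom
  max(min(off, 0.5), -0.5)
}

# Value of the same parabola at its vertex.
parabolic_peak_value <- function(ym1, y0, yp1) {
  off <- parabolic_vertex(ym1, y0, yp1)
  y0 - 0.25 * (ym1 - yp1) * off
}

`%||%` <- function(a, b) if (is.null(a)) b else a
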