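# Synthetic behavioral tables: social-interaction phase times and
# sucrose/water consumption, with group effects on the phase-2/phase-1
# ratio so defeated groups produce both susceptible and resilient animals.

#' Generate a synthetic behavior table
#'
#' Phase-1 interaction-zone times are drawn from a truncated normal;
#' phase-2 times are the phase-1 time multiplied by a log-normal ratio
#' whose mean is the group effect (so the expected SI ratio of a group
#' equals its effect).  Sucrose preference increases with the SI ratio,
#' emulating the co-occurrence of social avoidance and anhedonia.
#'
#' @param n_per_group animals per group.
#' @param group_effects named numeric vector of mean SI ratios per group
#'   (default `c(ND = 1.05, CSDS = 0.85)`); names are the group labels.
#' @param defeated named logical vector marking defeated groups (default:
#'   every group except `"ND"` is defeated).
#' @param ratio_sdlog log-normal spread of the per-animal SI ratio
#'   (default 0.4; at the default defeated effect this yields roughly
#'   70/30 susceptible/resilient).
#' @param phase1_mean,phase1_sd phase-1 zone-time distribution in seconds
#'   (default 60 +/- 15, truncated to [5, 145]; phases last 150 s).
#' @param seed integer seed.
#' @return A data frame with columns `animal_id`, `group`, `defeated`,
#'   `phase1_s`, `phase2_s`, `sucrose_ml`, `water_ml`.
#' @examples
#' b <- generate_behavior(8, seed = 1)
#' score_behavior(b)[1:3, ]
#' @export
generate_behavior <- function(n_per_group,
                              group_effects = c(ND = 1.05, CSDS = 0.85),
                              defeated = NULL,
                              ratio_sdlog = 0.4,
                              phase1_mean = 60, phase1_sd = 15,
                              seed = 1L) {
  assert_scalar(n_per_group, "n_per_group", lower = 1)
  if (!is.numeric(group_effects) || is.null(names(group_effects)) ||
      any(group_effects <= 0)) {
    dg_stop("`group_effects` must be a named vector of positive mean SI ratios")
  }
  if (is.null(defeated)) {
    defeated <- names(group_effects) != "ND"
    names(defeated) <- names(group_effects)
  }
  assert_scalar(ratio_sdlog, "ratio_sdlog", lower = 0)
  with_seed(seed, {
    rows <- lapply(names(group_effects), function(g) {
      n <- n_per_group
      p1 <- pmin(pmax(stats::rnorm(n, phase1_mean, phase1_sd), 5), 145)
      ratio <- stats::rlnorm(n, meanlog = log(group_effects[[g]]) -
                               ratio_sdlog^2 / 2, sdlog = ratio_sdlog)
      p2 <- pmin(p1 * ratio, 150)
      si <- p2 / p1
      pref <- pmin(pmax(50 + 20 * pmin(si, 1.5) + stats::rnorm(n, 0, 8),
                        1), 99)
      total <- stats::runif(n, 3, 5)
      data.frame(
        animal_id = sprintf("%s_m%03d", gsub("[^A-Za-z0-9]+", "", g),
                            seq_len(n)),
        group = g,
        defeated = isTRUE(defeated[[g]]),
        phase1_s = p1, phase2_s = p2,
        sucrose_ml = total * pref / 100,
        water_ml = total * (1 - pref / 100),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
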