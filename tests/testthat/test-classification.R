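# Threshold classifier: decision rules with boundary/tie behavior,
# precedence modes, partition and monotonicity properties, and the
# data-driven bimodal AHP threshold.

feat <- function(ttp, bi, ahp = 90, flags = character(0)) {
  list(trough_to_peak_ms = ttp, burst_index = bi, ahp_uv_per_ms = ahp,
       flags = flags)
}

test_that("the three-stage rules reproduce the published boundaries", {
  cfg <- classifier_config()
  expect_equal(classify_unit(feat(0.30, 0.5), cfg), "putative_PV")
  expect_equal(classify_unit(feat(0.40, 0.5), cfg), "putative_PV")   # <= 0.4
  expect_equal(classify_unit(feat(0.60, 2.5, 50), cfg), "putative_mossy")
  expect_equal(classify_unit(feat(0.60, 2.5, 90), cfg), "putative_granule")
  expect_equal(classify_unit(feat(0.60, 2.5, 70), cfg), "putative_granule")  # tie
  expect_equal(classify_unit(feat(0.60, 1.8), cfg), "wide_interneuron")  # not > 1.8
  expect_equal(classify_unit(feat(0.60, 1.0), cfg), "wide_interneuron")
  expect_equal(classify_unit(feat(0.60, Inf, 40), cfg), "putative_mossy")
  expect_equal(classify_unit(feat(0.60, 2.5, NA,
                                  flags = "degenerate_waveform"), cfg),
               "unclassifiable")
  expect_error(classify_unit(feat(NA, 2.5), cfg),
               class = "dg_contract_error")
})

test_that("precedence decides narrow-and-bursting units", {
  f <- feat(0.30, 3.0, 90)
  expect_equal(classify_unit(f, classifier_config(precedence = "latency_first")),
               "putative_PV")
  expect_equal(classify_unit(f, classifier_config(precedence = "bi_first")),
               "putative_granule")
})

test_that("raising thresholds never increases downstream counts", {
  set.seed(7)
  tab <- data.frame(unit_id = sprintf("u%03d", 1:300),
                    ttp_ms = runif(300, 0.1, 1.0),
                    burst_index = runif(300, 0, 5),
                    ahp_uv_per_ms = runif(300, 30, 110),
                    flags = "", stringsAsFactors = FALSE)
  excit <- function(bi_thr) {
    cl <- classify_cohort(tab, classifier_config(bi_threshold = bi_thr))
    sum(cl$counts[c("putative_mossy", "putative_granule")])
  }
  gran <- function(ahp_thr) {
    classify_cohort(tab, classifier_config(
      ahp_threshold_uv_per_ms = ahp_thr))$counts[["putative_granule"]]
  }
  for (pair in list(c(1, 2), c(1.8, 2.5), c(2.5, 4))) {
    expect_gte(excit(pair[1]), excit(pair[2]))
  }
  for (pair in list(c(50, 70), c(70, 90))) {
    expect_gte(gran(pair[1]), gran(pair[2]))
  }
})

test_that("labels partition every cohort: counts sum to the input size", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(5:120, 1)
    tab <- data.frame(unit_id = sprintf("u%03d", seq_len(n)),
                      ttp_ms = runif(n, 0.1, 1.2),
                      burst_index = c(runif(n - 1, 0, 6), Inf),
                      ahp_uv_per_ms = runif(n, 20, 130),
                      flags = sample(c("", "degenerate_waveform"), n,
                                     replace = TRUE, prob = c(0.9, 0.1)),
                      stringsAsFactors = FALSE)
    cl <- classify_cohort(tab)
    expect_identical(sum(cl$counts), n)
    expect_true(all(cl$units$class %in% cell_class_labels()))
  }
})

test_that("an all-narrow cohort is pure putative PV", {
  tab <- data.frame(unit_id = sprintf("u%02d", 1:30),
                    ttp_ms = runif(30, 0.15, 0.38),
                    burst_index = runif(30, 0, 6),
                    ahp_uv_per_ms = runif(30, 30, 110),
                    stringsAsFactors = FALSE)
  cl <- classify_cohort(tab)
  expect_identical(cl$counts[["putative_PV"]], 30L)
  expect_identical(sum(cl$counts[c("putative_mossy", "putative_granule")]), 0L)
})

test_that("bimodal valley detection recovers symmetric mixture midpoints", {
  set.seed(11)
  x <- c(rnorm(300, 40, 5), rnorm(300, 100, 5))
  thr <- detect_bimodal_threshold(x)
  expect_lt(abs(as.numeric(thr) - 70), 5)
  y <- c(rnorm(300, 0, 1), rnorm(300, 10, 1))
  expect_lt(abs(as.numeric(detect_bimodal_threshold(y)) - 5), 1)
  expect_error(detect_bimodal_threshold(rnorm(400, 70, 10)),
               class = "dg_no_bimodality")
  expect_error(detect_bimodal_threshold(rnorm(10)),
               class = "dg_param_error")
})

test_that("a mixture-model fit agrees with the density-valley threshold", {
  skip_if_not_installed("mclust")
  set.seed(12)
  x <- c(rnorm(300, 40, 5), rnorm(300, 100, 5))
  thr <- as.numeric(detect_bimodal_threshold(x))
  mclustBIC <- mclust::mclustBIC  # Mclust looks this up in the caller
  fit <- mclust::Mclust(x, G = 2, verbose = FALSE)
  mid <- mean(fit$parameters$mean)  # equal mixture, equal sd: midpoint
  expect_lt(abs(thr - mid), 5)
})

test_that("data-driven threshold mode recovers and reports the split point", {
  set.seed(5)
  n <- 150
  tab <- data.frame(
    unit_id = sprintf("u%03d", 1:(2 * n)),
    ttp_ms = runif(2 * n, 0.5, 0.9),
    burst_index = runif(2 * n, 2, 6),
    ahp_uv_per_ms = c(rnorm(n, 40, 5), rnorm(n, 100, 5)),
    stringsAsFactors = FALSE)
  cl <- classify_cohort(tab, classifier_config(ahp_threshold_mode = "data_driven"))
  expect_lt(abs(cl$threshold_used - 70), 10)
  expect_equal(sum(cl$counts[c("putative_mossy", "putative_granule")]), 2 * n)
  # unimodal AHP falls back to the fixed threshold with a warning
  tab$ahp_uv_per_ms <- rnorm(2 * n, 70, 8)
  expect_warning(cl2 <- classify_cohort(
    tab, classifier_config(ahp_threshold_mode = "data_driven")),
    "data-driven")
  expect_equal(cl2$threshold_used, 70)
})

test_that("empty feature tables are rejected", {
  expect_error(classify_cohort(data.frame()), class = "dg_param_error")
})
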