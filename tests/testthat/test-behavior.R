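# Behavioral scoring: SI ratio, phenotype split, sucrose preference,
# marker correlations, and the behavior generator's distributions.

test_that("SI ratio is phase2 over phase1, undefined at zero phase1", {
  expect_equal(si_ratio(50, 25), 0.5)
  expect_equal(si_ratio(60, 60), 1.0)
  expect_error(si_ratio(0, 30), class = "dg_undefined_ratio")
})

test_that("SI ratio is invariant under common scaling of both phases", {
  set.seed(3)
  for (i in 1:20) {
    p1 <- runif(1, 1, 150); p2 <- runif(1, 0, 150); k <- runif(1, 0.1, 5)
    expect_equal(si_ratio(k * p1, k * p2), si_ratio(p1, p2))
  }
})

test_that("phenotype split: under 1 susceptible, 1 and above resilient, gated on defeat", {
  expect_equal(assign_phenotype(0.5, TRUE), "susceptible")
  expect_equal(assign_phenotype(1.0, TRUE), "resilient")   # boundary
  expect_equal(assign_phenotype(1.7, TRUE), "resilient")
  expect_equal(assign_phenotype(0.5, FALSE), "not_applicable")
})

test_that("sucrose preference formula and bounds", {
  expect_equal(sucrose_preference(3, 1), 75)
  expect_equal(sucrose_preference(2, 2), 50)
  expect_equal(sucrose_preference(3, 0), 100)
  expect_error(sucrose_preference(0, 0), class = "dg_undefined_preference")
  set.seed(4)
  for (i in 1:20) {
    s <- runif(1, 0, 5); w <- runif(1, 0.01, 5)
    p <- sucrose_preference(s, w)
    expect_gte(p, 0); expect_lte(p, 100)
  }
})

test_that("scored tables partition defeated animals and keep excluded rows", {
  b <- generate_behavior(50, seed = 21)
  b$phase1_s[1] <- 0  # force one undefined ratio
  scored <- score_behavior(b)
  expect_equal(nrow(scored), nrow(b))            # nothing dropped
  expect_equal(scored$phenotype[1], "excluded")
  defined <- scored$defeated & scored$phenotype != "excluded"
  expect_true(all(scored$phenotype[defined] %in%
                    c("susceptible", "resilient")))
  expect_true(all(scored$phenotype[!scored$defeated &
                                     scored$phenotype != "excluded"] ==
                    "not_applicable"))
  expect_true(all(scored$sucrose_pref_pct >= 0 &
                    scored$sucrose_pref_pct <= 100, na.rm = TRUE))
})

test_that("behavior generation is deterministic and matches its effect sizes", {
  expect_identical(generate_behavior(20, seed = 9),
                   generate_behavior(20, seed = 9))
  # degenerate effect: phase-2 ratio distribution has mean 1
  b <- generate_behavior(1000, group_effects = c(CSDS = 1.0), seed = 31)
  scored <- score_behavior(b)
  expect_lt(abs(mean(scored$si_ratio) - 1), 0.05)
  # halved phase-2 mean: the vast majority is susceptible
  b2 <- score_behavior(generate_behavior(1000,
                                         group_effects = c(CSDS = 0.5),
                                         seed = 32))
  expect_gt(mean(b2$phenotype == "susceptible"), 0.8)
  # defaults produce both phenotypes in the defeated group
  b3 <- score_behavior(generate_behavior(200, seed = 33))
  tab <- table(b3$phenotype[b3$defeated])
  expect_gt(tab[["susceptible"]], 0)
  expect_gt(tab[["resilient"]], 0)
})

test_that("marker correlations: identity, anti-identity, and listwise deletion", {
  set.seed(6)
  si <- rlnorm(40, 0, 0.3)
  r1 <- marker_behavior_correlation(si, si)
  expect_equal(r1$r, 1)
  r2 <- marker_behavior_correlation(2 - si, si)
  expect_equal(r2$r, -1)
  si[3] <- NA
  r3 <- marker_behavior_correlation(rnorm(40), si)
  expect_equal(r3$n, 39)
  expect_error(marker_behavior_correlation(rep(1, 10), rlnorm(10)),
               class = "dg_degenerate_variance")
})

test_that("estimated r is unbiased for bivariate normal pairs at the published n", {
  # 500 simulated cohorts with true r = -0.4, n = 61
  rho <- -0.4
  n <- 61
  est <- vapply(1:500, function(s) {
    set.seed(s)
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    marker_behavior_correlation(x, y)$r
  }, 0)
  expect_lt(abs(mean(est) - rho), 0.05)
})
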