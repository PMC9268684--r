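# Group statistics: D'Agostino-Pearson normality (frozen independent
# oracle values), ANOVA/Bonferroni, Kruskal-Wallis/Dunn, type-II two-way
# ANOVA, and the per-class firing workflow.

test_that("D'Agostino-Pearson matches frozen reference values", {
  # expected statistics computed once with an independent implementation
  # of the 1990 omnibus test on these exact seeded samples
  set.seed(101); x1 <- round(rnorm(50), 6)
  set.seed(202); x2 <- round(rexp(40), 6)
  set.seed(303); x3 <- round(rt(30, df = 3), 6)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 3.5333961903743227, tolerance = 1e-10)
  expect_equal(r1$p_value, 0.1708963416979448, tolerance = 1e-10)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 8.66843274436052, tolerance = 1e-10)
  expect_equal(r2$p_value, 0.013112145089807627, tolerance = 1e-10)
  r3 <- dagostino_pearson(x3)
  expect_equal(r3$statistic, 1.115839758805849, tolerance = 1e-10)
  expect_equal(r3$p_value, 0.572398484227802, tolerance = 1e-10)
})

test_that("normality gate: small samples error out; skewed data fail the gate", {
  expect_error(dagostino_pearson(rnorm(5)), class = "dg_small_sample")
  expect_error(normality_gate(rnorm(20), rep(c("a", "b"), c(15, 5))),
               class = "dg_small_sample")
  # strong skew is rejected with high power at n = 100
  rej <- vapply(1:200, function(s) {
    set.seed(s)
    dagostino_pearson(rexp(100))$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.85)
  set.seed(1)
  g <- normality_gate(c(rnorm(50), rexp(50)^3), rep(c("a", "b"), each = 50))
  expect_false(g$pass)
  expect_named(g$p_values, c("a", "b"))
})

test_that("one-way ANOVA F equals a from-scratch sums-of-squares computation", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:5, 1)
    g <- rep(letters[1:k], times = sample(3:12, k, replace = TRUE))
    y <- rnorm(length(g)) + as.integer(factor(g)) * runif(1, 0, 1)
    res <- one_way_anova_bonferroni(y, g)
    gm <- mean(y)
    means <- tapply(y, g, mean)
    n_g <- table(g)
    ss_b <- sum(n_g * (means - gm)^2)
    ss_w <- sum((y - means[g])^2)
    f_oracle <- (ss_b / (k - 1)) / (ss_w / (length(y) - k))
    expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  }
})

test_that("overwhelming group separation gives a vanishing p-value", {
  set.seed(2)
  y <- c(rnorm(20, 0), rnorm(20, 5))
  g <- rep(c("a", "b"), each = 20)
  expect_lt(one_way_anova_bonferroni(y, g)$p_value, 1e-6)
  expect_error(one_way_anova_bonferroni(rep(c(1, 2), each = 5),
                                        rep(c("a", "b"), each = 5)),
               class = "dg_degenerate_variance")
})

test_that("Bonferroni post hocs dominate their raw p-values", {
  for (seed in 1:15) {
    set.seed(seed)
    y <- rnorm(60)
    g <- rep(letters[1:4], 15)
    a <- one_way_anova_bonferroni(y, g)
    expect_true(all(a$posthoc$p_adjusted >= a$posthoc$p_raw - 1e-15))
    expect_true(all(a$posthoc$p_adjusted ==
                      pmin(1, a$posthoc$p_raw * nrow(a$posthoc))))
    k <- kruskal_dunn(y, g)
    expect_true(all(k$posthoc$p_adjusted >= k$posthoc$p_raw - 1e-15))
  }
})

test_that("tie-corrected H matches a brute-force rank computation", {
  for (seed in 1:50) {
    set.seed(seed)
    y <- sample(1:6, 45, replace = TRUE)  # heavy ties
    g <- rep(letters[1:3], each = 15)
    if (length(unique(y)) == 1L) next
    res <- kruskal_dunn(y, g)
    r <- rank(y)
    n <- length(y)
    h_raw <- 12 / (n * (n + 1)) *
      sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
    ties <- table(y)
    h_oracle <- h_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
    expect_equal(res$statistic, h_oracle, tolerance = 1e-10)
  }
})

test_that("for two groups Dunn's z-square equals the Kruskal-Wallis H", {
  for (seed in 1:10) {
    set.seed(seed)
    y <- c(rnorm(12), rnorm(15, 0.5))
    g <- rep(c("a", "b"), c(12, 15))
    res <- kruskal_dunn(y, g)
    expect_equal(res$posthoc$z^2, res$statistic, tolerance = 1e-10)
  }
  expect_error(kruskal_dunn(rep(3, 20), rep(c("a", "b"), 10)),
               class = "dg_degenerate_variance")
})

test_that("a location-shifted group is detected with high power", {
  rej <- vapply(1:100, function(s) {
    set.seed(s)
    y <- c(rnorm(30), rnorm(30), rnorm(30, 2))
    g <- rep(letters[1:3], each = 30)
    kruskal_dunn(y, g)$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.9)
})

test_that("type-II two-way ANOVA equals sequential SS when balanced and car when not", {
  set.seed(8)
  # balanced: type II == type I
  a <- rep(c("x", "y"), each = 20)
  b <- rep(rep(c("u", "v"), each = 10), 2)
  y <- rnorm(40) + (a == "y") * 0.8 + (b == "v") * 0.5
  res <- two_way_anova(y, a, b)
  seq_tab <- anova(lm(y ~ factor(a) * factor(b)))
  expect_equal(res$effects$sum_sq, seq_tab$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_equal(res$effects$p, seq_tab$`Pr(>F)`[1:3], tolerance = 1e-10)

  skip_if_not_installed("car")
  # unbalanced: agree with car::Anova type II
  keep <- -c(1, 2, 21, 25, 26)
  y2 <- y[keep]; a2 <- a[keep]; b2 <- b[keep]
  res2 <- two_way_anova(y2, a2, b2)
  car_tab <- car::Anova(lm(y2 ~ factor(a2) * factor(b2)), type = 2)
  expect_equal(res2$effects$sum_sq, car_tab$`Sum Sq`[1:3], tolerance = 1e-8)
  expect_equal(res2$effects$p, car_tab$`Pr(>F)`[1:3], tolerance = 1e-8)
})

test_that("two-way ANOVA validates its design and supports subject blocking", {
  a <- rep(c("x", "y"), each = 6)
  b <- rep(c("u", "v"), 6)
  y <- rnorm(12)
  expect_error(two_way_anova(y[a == "x" | b == "u"],
                             a[a == "x" | b == "u"],
                             b[a == "x" | b == "u"]),
               class = "dg_design_error")
  subj <- rep(sprintf("s%d", 1:6), each = 2)
  res <- two_way_anova(c(rnorm(6), rnorm(6) + 1),
                       rep(c("pre", "post"), 6),
                       rep(c("ctl", "trt"), each = 6),
                       subject = subj)
  expect_equal(res$test_name, "two_way_anova_rm")
  expect_true(all(is.finite(res$effects$F)))
})

test_that("the firing workflow routes per class and skips unrepresented classes", {
  set.seed(14)
  units <- data.frame(
    class = rep(c("putative_PV", "putative_granule", "putative_mossy"),
                each = 40),
    group = rep(rep(c("ND", "Sus"), each = 20), 3),
    rate_hz = c(rlnorm(40, log(10), 0.3),          # skewed -> nonparametric
                rnorm(40, 2, 0.3), rnorm(40, 4, 0.5)),
    stringsAsFactors = FALSE)
  units <- units[!(units$class == "putative_mossy" & units$group == "Sus"), ]
  expect_warning(st <- compare_firing_by_group(units), "putative_mossy")
  expect_setequal(unique(st$class), c("putative_PV", "putative_granule"))
  expect_true(all(st$test_name %in% c("one_way_anova_bonferroni",
                                      "kruskal_wallis_dunn")))
  expect_true(all(st$p_adjusted >= st$p_value - 1e-15))
  omnibus <- st[st$comparison == "omnibus", ]
  expect_equal(nrow(omnibus), 2)
})
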