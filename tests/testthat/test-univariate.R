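test_that("star coding is a pure step function of p", {
  expect_equal(starCode(c(0.06, 0.049, 0.009, 0.0009, 1)),
               c("ns", "*", "**", "***", "ns"))
  expect_equal(starCode(c(0.05, 0.01, 0.001)), c("ns", "*", "**"))
})

test_that("normality test accepts normal samples and rejects bimodal ones", {
  set.seed(1)
  accept <- mean(replicate(100, ksNormality(rnorm(100))$p > 0.05))
  expect_gte(accept, 0.90)
  set.seed(2)
  bimodal <- c(rnorm(50, -10, 0.1), rnorm(50, 10, 0.1))
  expect_lt(ksNormality(bimodal)$p, 0.01)
  expect_error(ksNormality(c(1, 2, 3)), "n >= 4")
  expect_equal(ksNormality(rep(1, 10))$flag, "zero_variance")
})

test_that("Levene's test detects unequal variances", {
  x <- rep(c(1, 2, 3), 2)
  g <- rep(c("a", "b"), each = 3)
  l <- leveneP(x, g)
  expect_equal(l$statistic, 0)
  expect_equal(l$p, 1)
  set.seed(3)
  rej <- mean(replicate(40, {
    leveneP(c(rnorm(50, 0, 1), rnorm(50, 0, 10)),
            rep(c("a", "b"), each = 50))$p < 0.001
  }))
  expect_gte(rej, 0.95)
  # precondition boundary: two groups of two
  expect_true(is.finite(leveneP(c(1, 2, 4, 9), c("a", "a", "b", "b"))$p))
  expect_error(leveneP(1:5, rep("a", 5)), "2 groups")
})

test_that("two-group comparison gates between t and Mann-Whitney", {
  a <- c(1.2, 1.9, 3.1, 4.2, 5.0, 6.1)
  r <- compareTwoGroups(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$stars, "ns")
  expect_true(r$test %in% c("t", "welch_t"))
  # forced Mann-Whitney with the enumeration-oracle example
  r2 <- compareTwoGroups(c(1, 2, 3), c(4, 5, 6), forceTest = "mann_whitney")
  expect_equal(r2$test, "mann_whitney_u")
  expect_equal(r2$p, 0.1)
  expect_equal(r2$p, mwExactOracle(c(1, 2, 3), c(4, 5, 6)))
  expect_error(compareTwoGroups(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("exact Mann-Whitney p equals exhaustive enumeration (property)", {
  set.seed(4)
  for (i in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:10, 1)
    a <- round(rnorm(n1, 0, 2), 2)
    b <- round(rnorm(n2, 1, 2), 2)
    if (any(duplicated(c(a, b)))) next    # exact path requires no ties
    r <- compareTwoGroups(a, b, forceTest = "mann_whitney")
    expect_equal(r$p, mwExactOracle(a, b), tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }
})

test_that("two-group comparison holds its nominal size under the null", {
  set.seed(5)
  rej <- mean(replicate(600, {
    compareTwoGroups(rnorm(10), rnorm(10))$p < 0.05
  }))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("group comparison detects the day-1 receptor effect", {
  # power against the simulated day-1 IGF1R contrast
  hits <- 0; reps <- 40
  for (s in seq_len(reps)) {
    e <- simulateExpression(SimulationConfig(seed = 4000 + s))
    d1 <- e[e$day == 1 & e$gene == "IGF1R", ]
    r <- compareTwoGroups(d1$rel_abundance[d1$group == "control"],
                          d1$rel_abundance[d1$group == "rbst"])
    hits <- hits + (r$p < 0.05)
  }
  expect_gte(hits / reps, 0.8)
})

test_that("one-way ANOVA covers the three-group design", {
  x <- rep(c(5, 6, 7), 3)
  g <- rep(c("ctl", "rbst", "ext"), each = 3)
  r <- oneWayAnova(x, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  set.seed(6)
  rej <- mean(replicate(40, {
    oneWayAnova(c(rnorm(10), rnorm(10), rnorm(10, 5)),
                rep(c("a", "b", "c"), each = 10))$p < 0.001
  }))
  expect_gte(rej, 0.95)
  expect_error(oneWayAnova(rnorm(10), rep(c("a", "b"), 5)), ">= 3 groups")
})

test_that("cycle yield table computes day-wise percentage differences", {
  d <- StudyDesign()
  days <- seq(-18, 222)
  yields <- rbind(
    data.frame(animal = "T1", group = "rbst", day = days, kg = 40),
    data.frame(animal = "T2", group = "rbst", day = days, kg = 40),
    data.frame(animal = "T3", group = "rbst", day = days, kg = 40),
    data.frame(animal = "C1", group = "control", day = days, kg = 32),
    data.frame(animal = "C2", group = "control", day = days, kg = 32),
    data.frame(animal = "C3", group = "control", day = days, kg = 32))
  ct <- suppressWarnings(cycleYieldTable(yields, d))
  expect_equal(ct$pct_diff_mean, rep(25, nrow(ct)))
  expect_equal(ct$pct_diff_sd, rep(0, nrow(ct)))
  expect_equal(ct$cycle, 0:16)
  # equal groups: difference is noise around zero
  yields$kg <- 35 + rnorm(nrow(yields), 0, 0.5)
  ct2 <- cycleYieldTable(yields, d)
  expect_lt(max(abs(ct2$pct_diff_mean)), 3)
})

test_that("per-day comparisons run across a simulated panel", {
  fit <- fitSimStudy(61)
  uni <- perDayComparisons(fit$panel, genes = c("IGF1R", "LTF"))
  expect_true(all(uni$n_control == 3 & uni$n_rbst == 6))
  expect_true(all(uni$p >= 0 & uni$p <= 1))
  # the receptor shows far more significant days than the null gene
  sig <- tapply(uni$p < 0.05, uni$gene, sum)
  expect_gt(sig["IGF1R"], sig["LTF"])
})
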