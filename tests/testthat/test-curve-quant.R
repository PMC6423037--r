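test_that("baseline correction recovers additive baselines", {
  # known baseline under a clean doubling curve (26 cycles keeps the signal
  # small enough that the baseline stays identifiable)
  f <- 100 + 0.001 * 2^(1:26)
  cb <- correctBaseline(f)
  expect_equal(cb$flag, "ok")
  expect_lt(abs(cb$baseline - 100) / 100, 0.01)
  # zero-baseline case
  f0 <- 0.001 * 2^(1:26)
  cb0 <- correctBaseline(f0)
  expect_lt(abs(cb0$baseline), 0.01)
  # flat curve
  expect_equal(correctBaseline(rep(50, 40))$flag, "no_amplification")
  set.seed(1)
  expect_equal(correctBaseline(rnorm(40, 50, 1))$flag, "no_amplification")
  expect_error(correctBaseline(c(1, 2, 3)), "10")
})

test_that("window of linearity sits in the exponential phase", {
  # pure exponential: any window is perfectly log-linear
  w <- findWindowOfLinearity(0.001 * 2^(1:30))
  expect_gt(w$r2, 0.999)
  expect_equal(diff(w$window) + 1 >= 4, TRUE)
  # logistic with plateau: window upper edge stays below 90% of the plateau
  set.seed(2)
  f <- simCurve(1e-4, 1.9, K = 3000, B = 0, noise = 1)
  w2 <- findWindowOfLinearity(f)
  expect_lt(f[w2$window[2]], 0.9 * max(f))
  # series with no rise above the noise floor
  set.seed(3)
  expect_null(findWindowOfLinearity(rnorm(40, 0, 1)))
})

test_that("per-sample efficiency estimation recovers the generating value", {
  # noiseless doubling: exact
  fe <- fitSampleEfficiency(0.001 * 2^(1:40), c(20, 25))
  expect_equal(fe$efficiency, 2, tolerance = 1e-9)
  expect_equal(fe$r2, 1, tolerance = 1e-9)
  # noisy logistic at E = 1.85 and E = 1.70: mean estimate within +-0.05
  for (Etrue in c(1.85, 1.70)) {
    set.seed(100 + round(Etrue * 100))
    es <- replicate(40, {
      cb <- correctBaseline(simCurve(10^runif(1, -6, -3), Etrue))
      fitSampleEfficiency(cb$corrected, cb$window)$efficiency
    })
    expect_lt(abs(mean(es) - Etrue), 0.05)
  }
  expect_error(fitSampleEfficiency(2^(1:40), c(5, 7)), "4 cycles")
})

test_that("amplicon efficiency summary excludes outliers by the median rule", {
  s <- summarizeAmpliconEfficiency(c(2, 2, 2))
  expect_equal(s$meanEfficiency, 2)
  expect_equal(s$nExcluded, 0)
  s2 <- summarizeAmpliconEfficiency(c(1.85, 1.86, 1.60))
  expect_equal(s2$meanEfficiency, mean(c(1.85, 1.86)), tolerance = 1e-12)
  expect_equal(s2$nExcluded, 1)
  expect_error(summarizeAmpliconEfficiency(numeric(0)))
  expect_error(summarizeAmpliconEfficiency(c(2, 2), flags = c("poor_fit",
                                                              "poor_fit")),
               "no ok fits")
})

test_that("Cq and N0 follow the closed form and the defining identity", {
  # noiseless F' = 0.001 * 2^c with threshold 1.024 crosses at cycle 10
  fe <- fitSampleEfficiency(0.001 * 2^(1:40), c(8, 12))
  cq <- (log10(1.024) - fe$intercept) / fe$slope
  expect_equal(cq, 10, tolerance = 1e-9)
  expect_equal(1.024 / 2^cq, 0.001, tolerance = 1e-12)
  # identity N0 * meanE^Cq = Nq for every quantified well
  set.seed(11)
  tab <- simCurveTable(25, 1.9)
  q <- quantifyCurves(tab)
  ok <- !is.na(q$fits$N0)
  meanE <- q$amplicons$meanEfficiency[match(q$fits$gene, q$amplicons$gene)]
  expect_true(all(abs(q$fits$N0[ok] * meanE[ok]^q$fits$Cq[ok] -
                        q$fits$Nq[ok]) < 1e-9 * q$fits$Nq[ok]))
})

test_that("known abundance ratios are recovered through quantification", {
  # two groups of wells with an 8-fold X0 ratio at E = 2
  set.seed(12)
  tab <- do.call(rbind, lapply(1:20, function(i) {
    x0 <- if (i <= 10) 8e-5 else 1e-5
    data.frame(well = sprintf("w%02d", i), sample = sprintf("s%02d", i),
               gene = "G1", cycle = 1:40,
               fluorescence = simCurve(x0, 2), hi = i <= 10)
  }))
  q <- quantifyCurves(tab)
  f <- merge(q$fits, unique(tab[, c("well", "hi")]))
  f <- f[!is.na(f$N0), ]
  ratio <- mean(f$N0[f$hi]) / mean(f$N0[!f$hi])
  expect_gt(ratio, 7.2); expect_lt(ratio, 8.8)
  # Cq difference of log2(8) = 3 cycles
  dcq <- mean(f$Cq[!f$hi]) - mean(f$Cq[f$hi])
  expect_equal(dcq, 3, tolerance = 0.3)
})

test_that("quantification is scale equivariant and monotone in X0", {
  set.seed(13)
  f <- simCurve(1e-4, 1.9)
  for (s in c(0.1, 10)) {
    cb1 <- correctBaseline(f); cb2 <- correctBaseline(s * f)
    expect_equal(cb2$baseline, s * cb1$baseline, tolerance = 0.05 * s * 60)
    fe1 <- fitSampleEfficiency(cb1$corrected, cb1$window)
    fe2 <- fitSampleEfficiency(cb2$corrected, cb2$window)
    expect_equal(fe2$efficiency, fe1$efficiency, tolerance = 1e-6)
  }
  # monotonicity: larger X0 -> smaller Cq, larger N0 (noiseless batch)
  x0s <- 10^seq(-6, -3, by = 1)
  tab <- do.call(rbind, lapply(seq_along(x0s), function(i)
    data.frame(well = paste0("w", i), sample = paste0("s", i), gene = "G1",
               cycle = 1:40,
               fluorescence = simCurve(x0s[i], 1.9, noise = 0.01))))
  q <- quantifyCurves(tab)
  ord <- order(q$fits$well)
  expect_true(all(diff(q$fits$Cq[ord]) < 0))
  expect_true(all(diff(q$fits$N0[ord]) > 0))
})

test_that("an unquantifiable amplicon in a batch is reported, not fatal", {
  set.seed(14)
  tab <- simCurveTable(6, 1.9)
  flat <- data.frame(well = "flat1", sample = "sF", gene = "G2",
                     cycle = 1:40, fluorescence = rnorm(40, 50, 1), x0 = 0)
  q <- quantifyCurves(rbind(tab, flat))
  g2 <- q$amplicons[q$amplicons$gene == "G2", ]
  expect_true(is.na(g2$meanEfficiency))
  expect_true(is.na(q$fits$N0[q$fits$gene == "G2"]))
  expect_equal(q$fits$flag[q$fits$gene == "G2"], "no_amplification")
})
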