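test_that("response kernel is a unimodal pulse with washout by 28 days", {
  profs <- defaultGeneProfiles()
  for (g in c("IGF1R", "CCND1", "TNF", "IL1B")) {
    p <- profs[[g]]
    expect_equal(responseKernel(p@peakDay, p), 1 + p@amplitude)
    expect_true(responseKernel(28, p) < 1 + 0.05 * p@amplitude)  # washed out
    tau <- seq(0, 28, by = 0.5)
    k <- responseKernel(tau, p)
    expect_true(all(k >= 1))
    expect_equal(which.max(k), which(tau == p@peakDay))
  }
  # non-responsive profile is identically 1
  expect_equal(responseKernel(c(0, 5, NA, 100), profs$LTF), rep(1, 4))
  # pre-onset and pre-dose (NA) give no effect
  p <- profs$CCND1
  expect_equal(responseKernel(c(NA, 0, p@onsetDays), p), rep(1, 3))
})

test_that("expression simulation is deterministic under seed", {
  cfg <- SimulationConfig(seed = 42)
  e1 <- simulateExpression(cfg)
  e2 <- simulateExpression(cfg)
  expect_identical(e1, e2)
  e3 <- simulateExpression(SimulationConfig(seed = 43))
  expect_false(identical(e1$abundance, e3$abundance))
})

test_that("detection patterns follow the gene roster", {
  e <- simulateExpression(SimulationConfig(seed = 7))
  never <- c("IGFBP3", "IGFBP5", "COL3A1", "ESR2")
  expect_true(all(!e$detected[e$gene %in% never]))
  always <- c("CCND1", "IGF1R", "TNF", "IL1B", "SIRT2", "LTF", "UXT")
  expect_true(all(e$detected[e$gene %in% always]))
  # IGF1: per-animal detection, treated animals only, matching the truth draw
  tr <- attr(e, "truth")
  ig <- e[e$gene == "IGF1", ]
  det <- tapply(ig$detected, ig$animal, unique)
  expect_equal(as.logical(det[rownames(tr$detectAnimal)]),
               unname(tr$detectAnimal[, "IGF1"]))
  expect_true(all(!ig$detected[ig$group == "control"]))
})

test_that("control animals and pre-dose days carry no treatment effect", {
  # with noise silenced, control samples sit exactly on baseline + animal
  profs <- defaultGeneProfiles()["CCND1"]
  profs$CCND1@baselineLog10Sd <- 0
  profs$CCND1@animalSd <- 0
  cfg <- SimulationConfig(seed = 1, profiles = c(
    profs, defaultGeneProfiles()[c("UXT", "RPS9", "GPAM")]),
    sampleLoadingSd = 0)
  e <- simulateExpression(cfg)
  cc <- e[e$gene == "CCND1", ]
  expect_equal(cc$abundance[cc$group == "control"],
               rep(10^-0.46, sum(cc$group == "control")))
  pre <- cc$day < 0
  expect_equal(cc$abundance[pre], rep(10^-0.46, sum(pre)))
  # treated post-dose days show the kernel exactly
  sched <- buildDoseSchedule(cfg@design)
  one <- cc[cc$group == "rbst" & cc$day == 9, ]
  expect_equal(one$abundance,
               rep(10^-0.46 * responseKernel(9, profs$CCND1), nrow(one)))
})

test_that("null generator (all amplitudes zero) is calibrated at type-I level", {
  profs <- defaultGeneProfiles()
  for (g in names(profs)) profs[[g]]@amplitude <- 0
  hits <- 0; total <- 0
  for (s in 1:30) {
    e <- simulateExpression(SimulationConfig(seed = 800 + s,
                                             profiles = profs))
    e <- e[e$detected & e$gene %in%
             c("CCND1", "IGF1R", "TNF", "IL1B", "LTF"), ]
    for (g in unique(e$gene)) for (d in c(1, 9, 23, 35, 84, 140, 219)) {
      x <- e[e$gene == g & e$day == d, ]
      p <- t.test(log10(x$rel_abundance[x$group == "rbst"]),
                  log10(x$rel_abundance[x$group == "control"]))$p.value
      hits <- hits + (p < 0.05); total <- total + 1
    }
  }
  expect_gt(total, 1000)
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.09)
})

test_that("yield model reduces to the exact Wood curve without noise", {
  ym <- YieldModel(animalScaleSd = 0, treatmentBoost = 0, dimSd = 0,
                   noiseSd = 0)
  cfg <- SimulationConfig(seed = 5, design = StudyDesign(nControl = 1,
                                                         nTreated = 1),
                          yieldModel = ym)
  y <- simulateYield(cfg)
  ctl <- y[y$animal == "C1", ]
  dim <- ctl$day + 70
  expect_equal(ctl$kg, 13.7 * dim^0.30 * exp(-0.004 * dim), tolerance = 1e-12)
})

test_that("zero treatment boost centres the production difference on zero", {
  ym <- YieldModel(treatmentBoost = 0)
  diffs <- sapply(1:25, function(s) {
    y <- simulateYield(SimulationConfig(seed = 900 + s, yieldModel = ym))
    ct <- cycleYieldTable(y, StudyDesign())
    mean(ct$pct_diff_mean)
  })
  expect_lt(abs(mean(diffs)), 5)
})

test_that("default yields reproduce the cycle-wise difference profile", {
  y <- simulateYield(SimulationConfig(seed = 2024))
  ct <- cycleYieldTable(y, StudyDesign())
  d <- setNames(ct$pct_diff_mean, ct$cycle)
  # rises after dosing begins; dips during the no-dose gap (cycle 6);
  # peaks late; declines after the last dose
  expect_gt(max(d[as.character(7:13)]), d["1"])
  expect_lt(d["6"], mean(d[c("4", "5")]))
  expect_lt(d["6"], mean(d[c("7", "8")]))
  expect_lt(d["16"], max(d[as.character(7:13)]))
})

test_that("simulated curves obey the exponential limit and the plate count", {
  # noiseless, no baseline, huge plateau, unit session factor => F = X0 E^c
  e <- data.frame(sample = "s1", animal = "A1", group = "control", day = 1,
                  gene = "g1", abundance = 2, detected = TRUE)
  cfg <- SimulationConfig(seed = 3, curveParams = list(
    efficiency = c(g1 = 2), plateauK = 1e18, baselineB = 0, noiseSd = 0,
    replicateSd = 0, x0Scale = 1e-4), sessionFactorSdLog = 0)
  cv <- simulateCurves(e, cfg)
  one <- cv[cv$replicate == 1, ]
  expect_equal(one$fluorescence, 2e-4 * 2^(1:40), tolerance = 1e-9)
  # a full 56-sample plate of 18 assays in triplicate = 3024 curves
  cfg2 <- SimulationConfig(seed = 4)
  ex <- simulateExpression(cfg2)
  sub <- ex[ex$sample %in% unique(ex$sample)[1:56], ]
  cv2 <- simulateCurves(sub, cfg2)
  expect_equal(length(unique(cv2$well)), 18 * 56 * 3)
  # undetected rows give flat baseline-only curves (noise-level range only)
  flat <- cv2[cv2$gene == "IGFBP3", ]
  ranges <- tapply(flat$fluorescence, flat$well, function(f) diff(range(f)))
  expect_lt(max(ranges), 10)
})

test_that("group exchangeability holds when all effects are removed", {
  profs <- defaultGeneProfiles()
  for (g in names(profs)) profs[[g]]@amplitude <- 0
  ym <- YieldModel(treatmentBoost = 0)
  e <- simulateExpression(SimulationConfig(seed = 77, profiles = profs,
                                           yieldModel = ym))
  cc <- e[e$gene == "CCND1", ]
  # permutation test on group labels at the animal level
  obs <- abs(mean(log10(cc$rel_abundance[cc$group == "rbst"])) -
               mean(log10(cc$rel_abundance[cc$group == "control"])))
  animals <- unique(cc$animal)
  set.seed(1)
  perm <- replicate(200, {
    lab <- sample(animals, 3)
    abs(mean(log10(cc$rel_abundance[!cc$animal %in% lab])) -
          mean(log10(cc$rel_abundance[cc$animal %in% lab])))
  })
  expect_gt(mean(perm >= obs), 0.05)
})
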