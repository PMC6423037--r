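# Shared fixtures and independent oracles for the test suite.

# logistic amplification curve with additive baseline and Gaussian noise,
# mirroring the generative model but written independently of the package
simCurve <- function(x0, E, K = 3000, B = 50, noise = 1, cycles = 40,
                     sessionFactor = 1) {
  Ec <- E^(seq_len(cycles))
  X <- x0 * Ec / (1 + x0 * (Ec - 1) / K)
  sessionFactor * (B + X) + rnorm(cycles, 0, noise)
}

# long-format curve table for a set of wells of one amplicon
simCurveTable <- function(n, E, x0range = c(-6, -2), gene = "G1", ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    x0 <- 10^runif(1, x0range[1], x0range[2])
    data.frame(well = sprintf("w%03d", i), sample = sprintf("s%03d", i),
               gene = gene, cycle = seq_len(40),
               fluorescence = simCurve(x0, E, ...), x0 = x0,
               stringsAsFactors = FALSE)
  }))
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all labelings
mwExactOracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  U <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- U(a, b)
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(i) U(pooled[i], pooled[-i]))
  pLow <- mean(us <= obs + 1e-9)
  pHigh <- mean(us >= obs - 1e-9)
  min(1, 2 * min(pLow, pHigh))
}

# a small fully-detected expression record table
toyRecords <- function(nSample = 4, genes = c("gA", "gB")) {
  g <- expand.grid(sample = paste0("s", seq_len(nSample)), gene = genes,
                   stringsAsFactors = FALSE)
  g$animal <- sub("s", "A", g$sample)
  g$group <- rep(c("control", "rbst"), length.out = nSample)[
    as.integer(sub("s", "", g$sample))]
  g$day <- 1
  g$rel_abundance <- seq_len(nrow(g))
  g$detected <- TRUE
  g
}

# samples x genes profile matrix for screening tests: baseline draws with the
# default profiles' dose effect applied at a given days-since-dose
profileDraws <- function(tau, n, genes, profiles = defaultGeneProfiles()) {
  out <- t(vapply(seq_len(n), function(i) {
    vapply(genes, function(g) {
      p <- profiles[[g]]
      eff <- if (is.na(tau)) 1 else responseKernel(tau, p)
      10^(p@baselineLog10Mean + rnorm(1, 0, p@animalSd) + log10(eff) +
            rnorm(1, 0, p@baselineLog10Sd))
    }, numeric(1))
  }, numeric(length(genes))))
  colnames(out) <- genes
  rownames(out) <- paste0("u", seq_len(n))
  out
}

# run the expression-route multivariate chain on one simulated study and
# return the fitted pieces (used by several multivariate/pipeline tests)
fitSimStudy <- function(seed, design = StudyDesign()) {
  cfg <- SimulationConfig(seed = seed, design = design)
  e <- simulateExpression(cfg)
  e <- e[!e$gene %in% referenceGenes(), ]
  e$rel_abundance[!e$detected] <- NA
  panel <- applyInclusionFilter(assembleExpressionMatrix(e))
  pp <- preprocessPareto(panel)
  pca <- fitPcaNipals(pp$X, 2)
  keep <- setdiff(rownames(pp$X), flagOutliers(pp$X, pca)$excluded)
  X <- pp$X[keep, , drop = FALSE]
  y <- pp$y[match(keep, rownames(pp$X))]
  model <- fitOplsda(X, y)
  list(panel = panel, pp = pp, pca = pca, X = X, y = y, model = model,
       splot = sPlot(model, X))
}
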