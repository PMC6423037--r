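# ---------------------------------------------------------------------------
# Synthetic longitudinal study generator
# ---------------------------------------------------------------------------

# evaluate expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' YieldModel: Wood-curve milk-yield backbone with a treatment plateau
#'
#' Daily yield for animal a on study day t is
#' `s_a * woodA * DIM^woodB * exp(-woodC * DIM) * (1 + treatmentBoost * r(t)) + noise`
#' where DIM (days in milk) is `t + dimAtFirstDose`, `s_a` is a per-animal
#' log-normal scale, and `r(t)` (treated animals only) ramps linearly from 0
#' at the first dose to 1 over `boostRiseDays` and decays exponentially
#' (`boostDecayDays`) whenever more than one dose interval has elapsed since
#' the last dose — producing the trough during the mid-study dosing gap and
#' the post-treatment decline.
#'
#' @slot woodA,woodB,woodC Wood lactation-curve parameters (scale kg,
#'   dimensionless, per day).
#' @slot animalScaleSd sd of the per-animal log-normal scale (natural log).
#' @slot treatmentBoost Maximum fractional yield increase.
#' @slot boostRiseDays,boostDecayDays Ramp-up / decay time scales (days).
#' @slot dimAtFirstDose,dimSd Days in milk at the first dose (mean, per-animal
#'   sd); identical for both groups so that a zero boost implies exchangeable
#'   yields.
#' @slot noiseSd Daily measurement noise (kg).
#' @export
setClass("YieldModel", representation(
  woodA = "numeric", woodB = "numeric", woodC = "numeric",
  animalScaleSd = "numeric", treatmentBoost = "numeric",
  boostRiseDays = "numeric", boostDecayDays = "numeric",
  dimAtFirstDose = "numeric", dimSd = "numeric", noiseSd = "numeric"
))

setValidity("YieldModel", function(object) {
  msg <- character()
  if (object@woodA <= 0) msg <- c(msg, "woodA must be > 0")
  if (object@woodC <= 0) msg <- c(msg, "woodC must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a YieldModel
#'
#' Defaults place the lactation peak (~37 kg/day) at 60--90 days in milk and
#' are calibrated so that the cycle-wise production difference between groups
#' peaks in the low-40% range late in the dosing period.
#'
#' @param woodA,woodB,woodC,animalScaleSd,treatmentBoost,boostRiseDays,boostDecayDays,dimAtFirstDose,dimSd,noiseSd
#'   See [YieldModel-class].
#' @return A [YieldModel-class].
#' @export
YieldModel <- function(woodA = 13.7, woodB = 0.30, woodC = 0.004,
                       animalScaleSd = 0.12, treatmentBoost = 0.45,
                       boostRiseDays = 28, boostDecayDays = 20,
                       dimAtFirstDose = 70, dimSd = 4, noiseSd = 2.5) {
  new("YieldModel", woodA = woodA, woodB = woodB, woodC = woodC,
      animalScaleSd = animalScaleSd, treatmentBoost = treatmentBoost,
      boostRiseDays = boostRiseDays, boostDecayDays = boostDecayDays,
      dimAtFirstDose = dimAtFirstDose, dimSd = dimSd, noiseSd = noiseSd)
}

#' SimulationConfig: everything a synthetic study needs
#'
#' @slot seed Integer seed fixing all randomness end-to-end.
#' @slot design A [StudyDesign-class].
#' @slot profiles Named list of [GeneProfile-class] (defaults:
#'   [defaultGeneProfiles()]); reference genes must be non-responsive.
#' @slot yieldModel A [YieldModel-class].
#' @slot curveParams Named list controlling raw-curve synthesis: `efficiency`
#'   (named per-gene vector in (1, 2]; drawn uniformly on \[1.7, 2\] if `NULL`),
#'   `plateauK`, `baselineB`, `noiseSd`, `cycles`, `x0Scale`, `replicateSd`.
#' @slot sessionSize Samples per qPCR session (plate), default 56.
#' @slot sessionFactorSdLog sd (natural log) of the multiplicative session
#'   factors, which are renormalised to geometric mean 1.
#' @slot sampleLoadingSd Per-sample RNA/cDNA loading effect (log10 sd) shared
#'   by every gene of a sample; it cancels in reference-normalised ratios but
#'   drives the strong between-gene Cq correlation that reference-gene
#'   validation relies on.
#' @export
setClass("SimulationConfig", representation(
  seed = "integer", design = "StudyDesign", profiles = "list",
  yieldModel = "YieldModel", curveParams = "list",
  sessionSize = "integer", sessionFactorSdLog = "numeric",
  sampleLoadingSd = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!all(vapply(object@profiles, is, logical(1), "GeneProfile")))
    msg <- c(msg, "profiles must be GeneProfile objects")
  refs <- intersect(referenceGenes(), names(object@profiles))
  if (any(vapply(object@profiles[refs], slot, logical(1), "responsive")))
    msg <- c(msg, "reference genes must be non-responsive")
  if (length(msg)) msg else TRUE
})

#' Create a SimulationConfig
#'
#' @param seed Integer seed.
#' @param design A [StudyDesign-class].
#' @param profiles Named list of [GeneProfile-class].
#' @param yieldModel A [YieldModel-class].
#' @param curveParams Overrides for the curve-synthesis parameters.
#' @param sessionSize Samples per session.
#' @param sessionFactorSdLog Session-factor spread (natural log scale).
#' @param sampleLoadingSd Per-sample loading spread (log10 scale).
#' @return A [SimulationConfig-class].
#' @export
SimulationConfig <- function(seed = 1L, design = StudyDesign(),
                             profiles = defaultGeneProfiles(),
                             yieldModel = YieldModel(),
                             curveParams = list(),
                             sessionSize = 56, sessionFactorSdLog = 0.25,
                             sampleLoadingSd = 0.15) {
  defaults <- list(efficiency = NULL, plateauK = 3000, baselineB = 50,
                   noiseSd = 1.0, cycles = 40L, x0Scale = 1e-4,
                   replicateSd = 0.05)
  defaults[names(curveParams)] <- curveParams
  new("SimulationConfig", seed = as.integer(seed), design = design,
      profiles = profiles, yieldModel = yieldModel, curveParams = defaults,
      sessionSize = as.integer(sessionSize),
      sessionFactorSdLog = sessionFactorSdLog,
      sampleLoadingSd = sampleLoadingSd)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed ", object@seed, "): ",
      length(object@profiles), " genes, ",
      nControl(object@design) + nTreated(object@design), " animals, ",
      length(samplingDays(object@design)), " sampling days\n", sep = "")
})

.animalIds <- function(design) {
  c(paste0("C", seq_len(design@nControl)),
    paste0("T", seq_len(design@nTreated)))
}

.animalGroups <- function(design) {
  stats::setNames(rep(c("control", "rbst"),
                      c(design@nControl, design@nTreated)),
                  .animalIds(design))
}

#' Simulate a longitudinal expression table
#'
#' For every animal, sampling day and gene draws
#' `log10(abundance) = baseline + animal effect + log10(responseKernel) + noise`,
#' where the kernel term applies to treated animals on post-dose days only and
#' only for doses that elicited a response (per-dose Bernoulli with the
#' profile's `responseProb`, shared across animals). Detection follows each
#' profile's detection model. Reference-relative abundance is also reported
#' (abundance divided by the geometric mean of the same sample's reference
#' genes).
#'
#' @param config A [SimulationConfig-class].
#' @return A `data.frame` with columns `sample`, `animal`, `group`, `day`,
#'   `days_since_dose`, `gene`, `abundance`, `rel_abundance`, `detected`, and
#'   a `"truth"` attribute (animal effects, per-dose response indicators,
#'   per-animal detection draws).
#' @export
simulateExpression <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  design <- config@design
  schedule <- buildDoseSchedule(design)
  days <- samplingDays(design)
  animals <- .animalIds(design)
  groups <- .animalGroups(design)
  genes <- names(config@profiles)
  refs <- intersect(referenceGenes(), genes)

  .withSeed(config@seed + 101L, {
    animalEff <- sapply(genes, function(g)
      stats::rnorm(length(animals), 0, config@profiles[[g]]@animalSd))
    rownames(animalEff) <- animals
    doseResponded <- sapply(genes, function(g) {
      pr <- config@profiles[[g]]
      if (pr@responsive) stats::runif(design@nDoses) < pr@responseProb
      else rep(FALSE, design@nDoses)
    })
    doseResponded <- matrix(doseResponded, nrow = design@nDoses,
                            dimnames = list(NULL, genes))
    detectAnimal <- sapply(genes, function(g) {
      pr <- config@profiles[[g]]
      switch(pr@detection,
             always = rep(TRUE, length(animals)),
             never = rep(FALSE, length(animals)),
             per_animal = groups == "rbst" &
               stats::runif(length(animals)) < pr@pDetect)
    })
    rownames(detectAnimal) <- animals

    tau <- daysSinceLastDose(schedule, days)
    doseIdx <- findInterval(days, doseDays(schedule))
    grid <- expand.grid(animal = animals, day = days, gene = genes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(grid)
    prof <- config@profiles[grid$gene]
    baseMean <- vapply(prof, slot, numeric(1), "baselineLog10Mean")
    baseSd <- vapply(prof, slot, numeric(1), "baselineLog10Sd")
    dayPos <- match(grid$day, days)
    grid$days_since_dose <- tau[dayPos]
    grid$group <- unname(groups[grid$animal])

    # kernel effect: treated animals, post-dose days, responding doses only
    eff <- rep(1, n)
    for (g in genes) {
      pr <- config@profiles[[g]]
      if (!pr@responsive || pr@amplitude == 0) next
      sel <- grid$gene == g & grid$group == "rbst" & !is.na(grid$days_since_dose)
      di <- doseIdx[dayPos[sel]]
      responded <- di >= 1L & doseResponded[pmax(di, 1L), g]
      k <- responseKernel(grid$days_since_dose[sel], pr)
      eff[sel] <- ifelse(responded, k, 1)
    }
    # per-sample loading effect, shared across genes (cancels in ratios)
    sampleIds <- paste0(grid$animal, "_d", grid$day)
    uniqSamples <- unique(sampleIds)
    loading <- stats::setNames(
      stats::rnorm(length(uniqSamples), 0, config@sampleLoadingSd),
      uniqSamples)
    log10ab <- baseMean + animalEff[cbind(grid$animal, grid$gene)] +
      log10(eff) + loading[sampleIds] + stats::rnorm(n, 0, baseSd)
    grid$abundance <- 10^log10ab
    grid$detected <- detectAnimal[cbind(grid$animal, grid$gene)]
    grid$sample <- paste0(grid$animal, "_d", grid$day)

    refGeo <- tapply(ifelse(grid$gene %in% refs, log(grid$abundance), NA),
                     grid$sample, mean, na.rm = TRUE)
    grid$rel_abundance <- grid$abundance / exp(refGeo[grid$sample])

    out <- grid[order(grid$day, grid$animal, grid$gene),
                c("sample", "animal", "group", "day", "days_since_dose",
                  "gene", "abundance", "rel_abundance", "detected")]
    rownames(out) <- NULL
    attr(out, "truth") <- list(animalEffects = animalEff,
                               doseResponded = doseResponded,
                               detectAnimal = detectAnimal,
                               sampleLoading = loading,
                               doseDays = doseDays(schedule))
    out
  })
}

#' Simulate daily milk yields
#'
#' See [YieldModel-class] for the generative model. Yields are generated for
#' every day of the recording window (conditioning start through follow-up
#' end).
#'
#' @param config A [SimulationConfig-class].
#' @return `data.frame` with columns `animal`, `group`, `day`, `kg` and a
#'   `"truth"` attribute (per-animal scales and days in milk at day 0).
#' @export
simulateYield <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  design <- config@design
  ym <- config@yieldModel
  schedule <- buildDoseSchedule(design)
  t0 <- design@firstDoseDay - design@conditioningDays
  t1 <- max(doseDays(schedule)) + design@followupDays
  days <- seq.int(t0, t1)
  animals <- .animalIds(design)
  groups <- .animalGroups(design)

  .withSeed(config@seed + 202L, {
    sA <- stats::setNames(exp(stats::rnorm(length(animals), 0, ym@animalScaleSd)),
                          animals)
    dim0 <- stats::setNames(ym@dimAtFirstDose +
                              stats::rnorm(length(animals), 0, ym@dimSd),
                            animals)
    tau <- daysSinceLastDose(schedule, days)
    ramp <- pmin(1, pmax(0, (days - design@firstDoseDay) / ym@boostRiseDays))
    over <- pmax(0, ifelse(is.na(tau), 0, tau) - design@doseIntervalDays)
    persist <- ifelse(is.na(tau), 0, exp(-over / ym@boostDecayDays))
    r <- ramp * persist

    grid <- expand.grid(animal = animals, day = days,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$group <- unname(groups[grid$animal])
    dim <- grid$day + dim0[grid$animal]
    wood <- ym@woodA * dim^ym@woodB * exp(-ym@woodC * dim)
    boost <- 1 + ym@treatmentBoost * r[match(grid$day, days)] *
      (grid$group == "rbst")
    grid$kg <- pmax(0, sA[grid$animal] * wood * boost +
                      stats::rnorm(nrow(grid), 0, ym@noiseSd))
    out <- grid[order(grid$day, grid$animal), c("animal", "group", "day", "kg")]
    rownames(out) <- NULL
    attr(out, "truth") <- list(animalScale = sA, dimAtDay0 = dim0)
    out
  })
}

#' Simulate raw amplification curves for an expression table
#'
#' Per gene-sample and replicate, the amplicon copy trajectory follows the
#' logistic `X(c) = X0 E^c / (1 + X0 (E^c - 1) / K)` and the observed
#' fluorescence is `session_factor * (B + X(c)) + Normal(0, noiseSd)`, with
#' `X0` proportional to the true abundance (times a small log-normal replicate
#' effect). Undetected gene-samples produce flat baseline-only curves.
#' Sessions are assigned by splitting samples, in order, into blocks of
#' `sessionSize`; one multiplicative factor per session (geometric mean 1) is
#' drawn and recorded in the `"truth"` attribute.
#'
#' @param expression Expression table from [simulateExpression()] (or any
#'   data frame with `sample`, `animal`, `group`, `day`, `gene`, `abundance`,
#'   `detected`).
#' @param config A [SimulationConfig-class].
#' @return Long `data.frame` (`well`, `sample`, `animal`, `group`, `day`,
#'   `session`, `gene`, `replicate`, `cycle`, `fluorescence`) with a `"truth"`
#'   attribute (per-gene efficiencies, session factors, per-well X0).
#' @export
simulateCurves <- function(expression, config) {
  stopifnot(is(config, "SimulationConfig"))
  cp <- config@curveParams
  genes <- unique(expression$gene)
  samples <- unique(expression$sample)
  session <- stats::setNames(
    paste0("S", (seq_along(samples) - 1L) %/% config@sessionSize + 1L),
    samples)

  .withSeed(config@seed + 303L, {
    eff <- cp$efficiency
    if (is.null(eff))
      eff <- stats::setNames(stats::runif(length(genes), 1.7, 2.0), genes)
    sess <- unique(session)
    sf <- exp(stats::rnorm(length(sess), 0, config@sessionFactorSdLog))
    sf <- stats::setNames(sf / geomMean(sf), sess)

    reps <- 3L
    base <- expression[rep(seq_len(nrow(expression)), each = reps), ]
    base$replicate <- rep(seq_len(reps), nrow(expression))
    base$well <- paste0(base$sample, "_", base$gene, "_r", base$replicate)
    x0 <- ifelse(base$detected,
                 base$abundance * cp$x0Scale *
                   exp(stats::rnorm(nrow(base), 0, cp$replicateSd)),
                 0)
    cyc <- seq_len(cp$cycles)
    # logistic amplification, vectorised as wells x cycles
    E <- unname(eff[base$gene])
    X0M <- x0 %o% rep(1, cp$cycles)
    EcM <- exp(log(E) %o% cyc)
    M <- (X0M * EcM) / (1 + X0M * (EcM - 1) / cp$plateauK)
    FL <- unname(sf[session[base$sample]]) * (cp$baselineB + M) +
      matrix(stats::rnorm(length(M), 0, cp$noiseSd), nrow(M))

    out <- data.frame(
      well = rep(base$well, cp$cycles),
      sample = rep(base$sample, cp$cycles),
      animal = rep(base$animal, cp$cycles),
      group = rep(base$group, cp$cycles),
      day = rep(base$day, cp$cycles),
      session = rep(unname(session[base$sample]), cp$cycles),
      gene = rep(base$gene, cp$cycles),
      replicate = rep(base$replicate, cp$cycles),
      cycle = rep(cyc, each = nrow(base)),
      fluorescence = as.vector(FL),
      stringsAsFactors = FALSE)
    out <- out[order(out$well, out$cycle), ]
    rownames(out) <- NULL
    attr(out, "truth") <- list(efficiency = eff, sessionFactors = sf,
                               x0 = stats::setNames(x0, base$well),
                               sessionOf = session)
    out
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper producing expression, yields and (optionally) raw
#' curves under a single seed.
#'
#' @param config A [SimulationConfig-class].
#' @param curves Also synthesise raw amplification curves (can be large).
#' @return List with `expression`, `yields`, optionally `curves`, plus
#'   `design`, `schedule` and a merged `truth` list.
#' @export
simulateStudy <- function(config = SimulationConfig(), curves = FALSE) {
  expr <- simulateExpression(config)
  yields <- simulateYield(config)
  out <- list(expression = expr, yields = yields,
              design = config@design,
              schedule = buildDoseSchedule(config@design),
              truth = c(attr(expr, "truth"), attr(yields, "truth")))
  if (curves) {
    cv <- simulateCurves(expr, config)
    out$curves <- cv
    out$truth <- c(out$truth, attr(cv, "truth"))
  }
  out
}

#' Write a simulated study to disk
#'
#' Long-format CSVs (`expression.csv`, `yields.csv`, optionally `curves.csv`)
#' plus `truth.json` with the generator's ground truth for use as a test
#' oracle.
#'
#' @param study Result of [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$expression, file.path(dir, "expression.csv"),
                   row.names = FALSE)
  utils::write.csv(study$yields, file.path(dir, "yields.csv"),
                   row.names = FALSE)
  if (!is.null(study$curves))
    utils::write.csv(study$curves, file.path(dir, "curves.csv"),
                     row.names = FALSE)
  truth <- study$truth
  truth <- lapply(truth, function(x) if (is.matrix(x))
    as.data.frame(x) else x)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
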