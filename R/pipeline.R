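# ---------------------------------------------------------------------------
# End-to-end orchestration and screening of unknown samples
# ---------------------------------------------------------------------------

#' Run the screening pipeline end to end
#'
#' Exactly one expression source must be supplied: a [SimulationConfig-class]
#' (simulate first), a raw amplification-curve table (quantified with
#' [quantifyCurves()]), or a pre-computed replicate-level N0 table. The
#' stages then run in order: curve quantification, session-factor
#' correction, reference-gene stability, replicate aggregation and
#' reference normalisation, matrix assembly with the zero-missing inclusion
#' filter, per-day univariate comparisons (and the cycle-wise yield table
#' when yields are available), and the multivariate screen (PCA outlier
#' rejection, OPLS-DA, CV-ANOVA, S-plot, biomarker ranking). When the
#' simulation source is used without raw-curve synthesis the three
#' curve-level stages are skipped (the simulator emits expression directly)
#' and recorded as such in the report.
#'
#' @param simulate A [SimulationConfig-class], or `NULL`.
#' @param curves Long raw-curve data frame (see [quantifyCurves()]), or
#'   `NULL`.
#' @param n0 Replicate-level N0 data frame (`sample`, `animal`, `group`,
#'   `day`, `session`, `gene`, `N0`, optional `flag`, `Cq`), or `NULL`.
#' @param yields Daily yield data frame, or `NULL` (generated when
#'   simulating).
#' @param design The [StudyDesign-class] (taken from `simulate` when given).
#' @param simulateRawCurves When simulating, also synthesise and quantify raw
#'   curves (slower, exercises the whole chain).
#' @param outDir Optional directory; every stage's outputs are written there.
#' @param alpha Significance level used throughout.
#' @param inclusionPct Allowed per-gene missingness (% ; default 0).
#' @param excludeGenes Genes excluded from the multivariate panel a priori.
#' @param pcorrThreshold S-plot panel threshold.
#' @return A `ScreenReport` list: `counts` (stage-by-stage records),
#'   `referenceStability`, `panelData` (the filtered
#'   [ExpressionPanel-class], with the filter report in its metadata),
#'   `univariate`, `cycleYield`, `multivariate`
#'   (preprocessing, PCA, outliers, OPLS-DA summary, S-plot), `panel`
#'   (ranked biomarkers), and `suspicious` (samples whose predictive score
#'   exceeds the control 95th percentile).
#' @export
runPipeline <- function(simulate = NULL, curves = NULL, n0 = NULL,
                        yields = NULL, design = NULL,
                        simulateRawCurves = FALSE, outDir = NULL,
                        alpha = 0.05, inclusionPct = 0,
                        excludeGenes = "CTNNAL1", pcorrThreshold = 0.4) {
  sources <- !vapply(list(simulate, curves, n0), is.null, logical(1))
  if (sum(sources) != 1L)
    stop("config error: exactly one of simulate / curves / n0 must be given")
  counts <- list()
  refReport <- NULL
  saveDir <- function(sub) {
    if (is.null(outDir)) return(NULL)
    d <- file.path(outDir, sub); dir.create(d, FALSE, TRUE); d
  }

  records <- NULL
  if (!is.null(simulate)) {
    design <- simulate@design
    study <- simulateStudy(simulate, curves = simulateRawCurves)
    yields <- study$yields
    if (!is.null(outDir)) writeSimulation(study, saveDir("simulation"))
    if (simulateRawCurves) curves <- study$curves
    else {
      # the simulator emits reference-relative abundance directly; reference
      # genes are consumed by that normalisation and are not target columns
      records <- study$expression[!study$expression$gene %in%
                                    referenceGenes(), ]
      records$rel_abundance[!records$detected] <- NA_real_
      counts$simulated_expression_rows <- nrow(records)
    }
  }
  .assert(!is.null(design), "a StudyDesign is required")

  if (!is.null(curves)) {
    counts$curves_wells <- length(unique(curves$well))
    quant <- quantifyCurves(curves)
    if (!is.null(outDir)) writeQuantification(quant, saveDir("curve_quant"))
    fits <- quant$fits
    counts$wells_ok <- sum(fits$flag == "ok")
    n0 <- fits[, intersect(c("well", "sample", "animal", "group", "day",
                             "session", "gene", "replicate", "flag",
                             "Cq", "N0"), names(fits))]
  }

  if (!is.null(n0)) {
    if (!"flag" %in% names(n0)) n0$flag <- "ok"
    counts$n0_rows <- nrow(n0)
    okN0 <- n0[n0$flag == "ok" & is.finite(n0$N0), ]
    if ("session" %in% names(n0) &&
        length(unique(okN0$session)) > 1L) {
      rm0 <- betweenSessionRatioMatrix(okN0)
      factors <- estimateSessionFactors(rm0)
      n0 <- applySessionFactors(n0, factors)
      if (!is.null(outDir))
        writeSessionFactors(factors, file.path(saveDir("session"),
                                               "session_factors.csv"), rm0)
      counts$sessions_corrected <- length(factors)
    }
    if ("Cq" %in% names(n0)) {
      refCq <- n0[n0$gene %in% referenceGenes() & is.finite(n0$Cq), ]
      if (nrow(refCq)) {
        agg <- stats::aggregate(Cq ~ sample + gene, refCq, mean)
        wide <- stats::reshape(agg, idvar = "sample", timevar = "gene",
                               direction = "wide")
        cqm <- as.matrix(wide[, -1, drop = FALSE])
        colnames(cqm) <- sub("^Cq\\.", "", colnames(cqm))
        rownames(cqm) <- wide$sample
        if (ncol(cqm) >= 2) {
          refReport <- flagReferenceSet(cqm)
          if (!is.null(outDir))
            writeReferenceReport(refReport, saveDir("reference_stability"))
        }
      }
    }
    records <- computeExpressionRecords(n0)
    counts$expression_records <- nrow(records)
  }

  panel0 <- assembleExpressionMatrix(records, design = design)
  counts$matrix_samples <- ncol(panel0)
  counts$matrix_genes <- nrow(panel0)
  panel <- applyInclusionFilter(panel0, maxMissingPct = inclusionPct,
                                excludeGenes = excludeGenes)
  counts$retained_genes <- nrow(panel)
  counts$retained_samples <- ncol(panel)
  if (!is.null(outDir)) writeExpressionPanel(panel, saveDir("expression"))

  uni <- perDayComparisons(panel)
  cyc <- if (!is.null(yields)) cycleYieldTable(yields, design) else NULL
  if (!is.null(outDir)) {
    utils::write.csv(uni, file.path(saveDir("univariate"),
                                    "per_day_tests.csv"), row.names = FALSE)
    if (!is.null(cyc))
      utils::write.csv(cyc, file.path(saveDir("univariate"),
                                      "cycle_yield.csv"), row.names = FALSE)
  }

  # multivariate screen
  pp <- preprocessPareto(panel)
  pca <- fitPcaNipals(pp$X, nComponents = min(2L, ncol(pp$X) - 1L))
  out <- flagOutliers(pp$X, pca, alpha = alpha)
  keep <- setdiff(rownames(pp$X), out$excluded)
  counts$outliers_removed <- length(out$excluded)
  X <- pp$X[keep, , drop = FALSE]
  y <- pp$y[match(keep, rownames(pp$X))]
  model <- fitOplsda(X, y)
  ca <- cvAnova(X, y, nOrth = model@nOrth)
  sp <- sPlot(model, X)
  ranked <- rankBiomarkers(sp, threshold = pcorrThreshold)
  controlScores <- model@scores[y == 0]
  suspicious <- rownames(X)[model@scores >
                              stats::quantile(controlScores, 1 - alpha)]
  counts$panel_size <- sum(ranked$in_panel)

  summary <- list(r2x = model@r2x, r2y = model@r2y, q2 = as.numeric(model@q2),
                  n_orth = model@nOrth,
                  cv_anova = ca[, c("F", "df1", "df2", "p")],
                  outliers = out$excluded)
  if (!is.null(outDir)) {
    d <- saveDir("multivariate")
    jsonlite::write_json(
      list(r2x = summary$r2x, r2y = summary$r2y, q2 = summary$q2,
           n_orth = summary$n_orth, cv_anova_F = ca$F, cv_anova_p = ca$p,
           outliers = out$excluded, panel = ranked$gene[ranked$in_panel]),
      file.path(d, "model_summary.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(ranked, file.path(d, "s_plot.csv"), row.names = FALSE)
  }

  list(counts = counts, referenceStability = refReport,
       panelData = panel,
       univariate = uni, cycleYield = cyc,
       multivariate = list(preprocess = pp, pca = pca, outliers = out,
                           model = model, cvAnova = ca, sPlot = sp,
                           trainX = X, trainY = y,
                           controlScores = controlScores),
       panel = ranked, suspicious = suspicious)
}

#' Screen unknown samples against a trained model
#'
#' Projects new samples through the stored preprocessing and OPLS-DA model
#' and flags those whose predictive score exceeds the given percentile of
#' the control population's scores -- samples with elevated panel-gene
#' expression that warrant follow-up. Samples missing a panel gene are
#' rejected with a reason rather than projected.
#'
#' @param fit Either a `ScreenReport` from [runPipeline()] or a list with
#'   elements `preprocess` (`preprocessedMatrix`), `model`
#'   ([OplsdaModel-class]) and `controlScores`.
#' @param newProfiles Samples x genes matrix (original abundance scale) of
#'   the unknowns; columns must cover the trained panel.
#' @param percentile Control-score percentile defining suspicion (default
#'   0.95).
#' @return Data frame `sample`, `score`, `threshold`, `flagged`, `reason`.
#' @export
screenUnknowns <- function(fit, newProfiles, percentile = 0.95) {
  if (!is.null(fit$multivariate)) fit <- fit$multivariate
  pp <- fit$preprocess
  model <- fit$model
  thr <- stats::quantile(fit$controlScores, percentile, names = FALSE)
  newProfiles <- as.matrix(newProfiles)
  ids <- rownames(newProfiles)
  if (is.null(ids)) ids <- paste0("unknown", seq_len(nrow(newProfiles)))
  res <- data.frame(sample = ids, score = NA_real_, threshold = thr,
                    flagged = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  panelGenes <- colnames(pp$X)
  usable <- rep(TRUE, nrow(newProfiles))
  miss <- setdiff(panelGenes, colnames(newProfiles))
  if (length(miss)) {
    res$reason <- paste("missing panel gene(s):", paste(miss, collapse = ","))
    return(res)
  }
  sub <- newProfiles[, panelGenes, drop = FALSE]
  bad <- apply(sub, 1, function(r) any(!is.finite(r) | r <= 0))
  res$reason[bad] <- "missing or non-positive panel value"
  if (any(!bad)) {
    Z <- .projectPareto(pp, sub[!bad, , drop = FALSE])
    core <- list(w = model@weights, Wo = model@orthoWeights,
                 Po = model@orthoLoadings, b = model@b)
    pr <- .oplsPredict(core, Z, model@yMean)
    res$score[!bad] <- pr$t
    res$flagged[!bad] <- pr$t > thr
  }
  res
}
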