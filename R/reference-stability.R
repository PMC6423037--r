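# ---------------------------------------------------------------------------
# BestKeeper-style reference-gene validation from Cq values
# ---------------------------------------------------------------------------

#' Cq descriptive statistics for one candidate reference gene
#'
#' The dispersion statistic `dev` follows the BestKeeper convention: the mean
#' absolute deviation of Cq from the gene's geometric mean Cq (in cycles).
#' The ordinary sample sd is reported alongside. A gene with `dev` above
#' `maxDev` (1 cycle by default) is judged `inconsistent`.
#'
#' @param cq Numeric vector of Cq values (n >= 3, finite).
#' @param gene Optional gene id carried into the result.
#' @param maxDev Inconsistency threshold in cycles.
#' @return One-row data frame: `gene`, `n`, `geoMeanCq`, `meanCq`, `minCq`,
#'   `maxCq`, `dev`, `sd`, `cv` (dev as % of geometric mean Cq), `verdict`.
#' @export
geneDescriptives <- function(cq, gene = NA_character_, maxDev = 1) {
  cq <- cq[is.finite(cq)]
  .assert(length(cq) >= 3, "need n >= 3 finite Cq values")
  g <- geomMean(cq)
  dev <- mean(abs(cq - g))
  data.frame(gene = gene, n = length(cq), geoMeanCq = g, meanCq = mean(cq),
             minCq = min(cq), maxCq = max(cq), dev = dev,
             sd = stats::sd(cq), cv = 100 * dev / g,
             verdict = if (dev > maxDev) "inconsistent" else "consistent",
             stringsAsFactors = FALSE)
}

#' BestKeeper index
#'
#' Per-sample geometric mean of the candidate reference genes' Cq values;
#' samples missing any candidate are excluded from the index.
#'
#' @param cqMatrix Numeric matrix, samples x candidate genes (>= 2 genes).
#' @return Named numeric vector over the complete samples.
#' @export
bestkeeperIndex <- function(cqMatrix) {
  cqMatrix <- as.matrix(cqMatrix)
  .assert(ncol(cqMatrix) >= 2, "need at least 2 candidate genes")
  complete <- stats::complete.cases(cqMatrix)
  apply(cqMatrix[complete, , drop = FALSE], 1, geomMean)
}

#' Correlate a candidate gene's Cq with the BestKeeper index
#'
#' Pearson correlation with a two-sided p-value from the t transform
#' (descriptive, no multiplicity correction, as in the cited tool).
#'
#' @param cq Candidate Cq values, aligned with `index`.
#' @param index BestKeeper index values.
#' @return List with `r`, `p`, `n` and `flag` (`"ok"` or `"zero_variance"`).
#' @export
correlateWithIndex <- function(cq, index) {
  keep <- is.finite(cq) & is.finite(index)
  cq <- cq[keep]; index <- index[keep]
  .assert(length(cq) >= 3, "need n >= 3 paired values")
  if (stats::sd(cq) == 0 || stats::sd(index) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(cq),
                flag = "zero_variance"))
  ct <- stats::cor.test(cq, index, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(cq), flag = "ok")
}

#' Judge a candidate reference-gene set
#'
#' Runs [geneDescriptives()] and [correlateWithIndex()] for every candidate
#' and recommends those that are both consistent (dev <= `maxDev`) and
#' strongly correlated with the index (r >= `minR`).
#'
#' @param cqMatrix Samples x candidate genes Cq matrix (>= 2 genes).
#' @param maxDev Dispersion threshold in cycles (default 1).
#' @param minR Correlation threshold (default 0.7).
#' @return List with `stability` (data frame), `index`, and `recommended`
#'   (character vector; empty with a warning when no candidate qualifies).
#' @export
flagReferenceSet <- function(cqMatrix, maxDev = 1, minR = 0.7) {
  cqMatrix <- as.matrix(cqMatrix)
  .assert(ncol(cqMatrix) >= 2, "need at least 2 candidate genes")
  idx <- bestkeeperIndex(cqMatrix)
  complete <- stats::complete.cases(cqMatrix)
  stab <- do.call(rbind, lapply(colnames(cqMatrix), function(g) {
    d <- geneDescriptives(cqMatrix[, g], gene = g, maxDev = maxDev)
    co <- correlateWithIndex(cqMatrix[complete, g], idx)
    d$r <- co$r; d$rP <- co$p
    d
  }))
  rec <- stab$gene[stab$verdict == "consistent" & !is.na(stab$r) &
                     stab$r >= minR]
  if (length(rec) == 0)
    warning("no candidate reference gene passed the stability criteria")
  list(stability = stab, index = idx, recommended = rec)
}

#' Write a reference-stability report
#'
#' @param result From [flagReferenceSet()].
#' @param dir Output directory; writes `reference_stability.csv` and
#'   `reference_verdicts.json`.
#' @return `dir`, invisibly.
#' @export
writeReferenceReport <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$stability,
                   file.path(dir, "reference_stability.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(recommended = result$recommended,
         verdicts = stats::setNames(as.list(result$stability$verdict),
                                    result$stability$gene)),
    file.path(dir, "reference_verdicts.json"), auto_unbox = TRUE)
  invisible(dir)
}
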