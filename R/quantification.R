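# ---------------------------------------------------------------------------
# From corrected N0 values to the relative-expression matrix
# ---------------------------------------------------------------------------

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom SummarizedExperiment "rowData<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

#' ExpressionPanel: relative expression with study metadata
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with one `relabund` assay (genes x samples; `NA` = undetected), sample
#' metadata in `colData` (`animal`, `group`, `day`, `days_since_dose`) and
#' per-gene detection completeness (% of samples detected) in `rowData`.
#'
#' @export
setClass("ExpressionPanel", contains = "SummarizedExperiment")

setValidity("ExpressionPanel", function(object) {
  msg <- character()
  need <- c("animal", "group", "day")
  if (!all(need %in% names(colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (!"completeness" %in% names(rowData(object)))
    msg <- c(msg, "rowData must contain completeness")
  cc <- rowData(object)$completeness
  if (length(cc) && (any(cc < 0) || any(cc > 100)))
    msg <- c(msg, "completeness must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Per-gene detection completeness of an ExpressionPanel
#' @param object An `ExpressionPanel`.
#' @return Named numeric vector (% of samples detected).
#' @export
setGeneric("completeness", function(object) standardGeneric("completeness"))
#' @export
setMethod("completeness", "ExpressionPanel", function(object)
  stats::setNames(rowData(object)$completeness, rownames(object)))

setMethod("show", "ExpressionPanel", function(object) {
  callNextMethod()
  cat("detection completeness: ",
      sum(rowData(object)$completeness == 100), "/", nrow(object),
      " genes fully detected\n", sep = "")
})

#' Aggregate replicate N0 values for one gene-sample
#'
#' Arithmetic mean of the `ok`-flagged replicate N0s (geometric optional);
#' undetected when no replicate is `ok`. The replicate CV (sd/mean of the
#' used replicates) is recorded.
#'
#' @param n0 Numeric vector of replicate N0 values (1--3 typically).
#' @param flags Character flags per replicate; `usable` flags are averaged
#'   (`"efficiency_outlier"` wells keep their N0 -- they are excluded only
#'   from the amplicon mean efficiency).
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @param usable Flag values treated as quantified.
#' @return List with `N0` (`NA` when undetected), `detected`, `n`, `cv`.
#' @export
aggregateReplicates <- function(n0, flags = rep("ok", length(n0)),
                                method = c("arithmetic", "geometric"),
                                usable = c("ok", "efficiency_outlier")) {
  method <- match.arg(method)
  use <- flags %in% usable & is.finite(n0)
  if (!any(use))
    return(list(N0 = NA_real_, detected = FALSE, n = 0L, cv = NA_real_))
  v <- n0[use]
  m <- if (method == "geometric") geomMean(v) else mean(v)
  list(N0 = m, detected = TRUE, n = length(v),
       cv = if (length(v) > 1) stats::sd(v) / mean(v) else NA_real_)
}

#' Reference-normalised relative expression
#'
#' The expression ratio of a target is its N0 divided by the geometric mean
#' of the three reference genes' N0s. Any undetected reference makes the
#' sample un-normalisable (`NA`, to be excluded downstream).
#'
#' @param n0Target Target N0 (vectorised).
#' @param n0Refs Numeric vector of the reference N0s (one sample), or a
#'   matrix with one row per element of `n0Target`.
#' @return Ratio(s); `NA` where a reference is missing or non-positive.
#' @examples
#' relativeExpression(3, c(2, 4, 8)) # 0.75
#' @export
relativeExpression <- function(n0Target, n0Refs) {
  if (is.matrix(n0Refs)) {
    ref <- apply(n0Refs, 1, function(r)
      if (all(is.finite(r) & r > 0)) geomMean(r) else NA_real_)
  } else {
    ref <- if (all(is.finite(n0Refs) & n0Refs > 0)) geomMean(n0Refs)
    else NA_real_
  }
  ifelse(is.na(ref), NA_real_, n0Target / ref)
}

#' Build expression records from an aggregated N0 table
#'
#' Aggregates replicates per sample x gene, then normalises every target gene
#' by the geometric mean of the reference genes within the same sample.
#'
#' @param n0 Data frame with columns `sample`, `gene`, `N0`, optional `flag`
#'   (default `"ok"`), and metadata columns (`animal`, `group`, `day`,
#'   `session`) carried through.
#' @param refGenes Reference gene ids (default [referenceGenes()]).
#' @param aggregate Replicate aggregation method, see
#'   [aggregateReplicates()].
#' @return Data frame of expression records (`sample`, metadata, `gene`,
#'   `rel_abundance`, `detected`), targets only.
#' @export
computeExpressionRecords <- function(n0, refGenes = referenceGenes(),
                                     aggregate = "arithmetic") {
  .assert(all(c("sample", "gene", "N0") %in% names(n0)),
          "n0 needs sample, gene, N0 columns")
  if (!"flag" %in% names(n0)) n0$flag <- "ok"
  meta <- intersect(c("animal", "group", "day", "session"), names(n0))
  agg <- do.call(rbind, lapply(
    split(n0, list(n0$sample, n0$gene), drop = TRUE), function(d) {
      a <- aggregateReplicates(d$N0, d$flag, method = aggregate)
      cbind(d[1, c("sample", "gene", meta), drop = FALSE],
            data.frame(N0 = a$N0, detected = a$detected, cv = a$cv))
    }))
  refWide <- stats::reshape(
    agg[agg$gene %in% refGenes, c("sample", "gene", "N0")],
    idvar = "sample", timevar = "gene", direction = "wide")
  refMat <- as.matrix(refWide[, -1, drop = FALSE])
  rownames(refMat) <- refWide$sample
  targets <- agg[!agg$gene %in% refGenes, , drop = FALSE]
  refRows <- refMat[match(targets$sample, rownames(refMat)), , drop = FALSE]
  targets$rel_abundance <- relativeExpression(targets$N0, refRows)
  targets$detected <- targets$detected & !is.na(targets$rel_abundance)
  targets$rel_abundance[!targets$detected] <- NA_real_
  rownames(targets) <- NULL
  targets[, c("sample", meta, "gene", "rel_abundance", "detected")]
}

#' Assemble the ExpressionPanel
#'
#' Pivots long expression records to a genes x samples matrix, attaches study
#' metadata (including days since the most recent dose via the design's
#' schedule) and computes per-gene detection completeness.
#'
#' @param records Data frame with `sample`, `animal`, `group`, `day`, `gene`,
#'   a value column (`rel_abundance`), and `detected`.
#' @param design Optional [StudyDesign-class] used to derive
#'   `days_since_dose`.
#' @return An [ExpressionPanel-class].
#' @export
assembleExpressionMatrix <- function(records, design = NULL) {
  need <- c("sample", "animal", "group", "day", "gene", "rel_abundance",
            "detected")
  .assert(all(need %in% names(records)),
          paste("records must contain:", paste(need, collapse = ", ")))
  if (anyDuplicated(records[c("sample", "gene")]))
    stop("duplicate (sample, gene) records")
  records$rel_abundance[!records$detected] <- NA_real_
  samples <- unique(records$sample)
  genes <- unique(records$gene)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(records$gene, genes), match(records$sample, samples))] <-
    records$rel_abundance
  first <- records[!duplicated(records$sample), ]
  cd <- DataFrame(animal = first$animal, group = first$group,
                  day = first$day, row.names = first$sample)[samples, ]
  if ("session" %in% names(records))
    cd$session <- first$session[match(samples, first$sample)]
  if (!is.null(design)) {
    sched <- buildDoseSchedule(design)
    cd$days_since_dose <- daysSinceLastDose(sched, cd$day)
  } else if ("days_since_dose" %in% names(records)) {
    cd$days_since_dose <- first$days_since_dose[match(samples, first$sample)]
  }
  rd <- DataFrame(completeness = 100 * rowMeans(!is.na(m)),
                  row.names = genes)
  new("ExpressionPanel",
      SummarizedExperiment(assays = list(relabund = m),
                           colData = cd, rowData = rd))
}

#' Apply the zero-missing inclusion filter
#'
#' Two deterministic steps, genes first: (1) drop target genes whose
#' detection completeness is below `100 - maxMissingPct` (plus any gene named
#' in `excludeGenes`); (2) drop samples with any missing value among the
#' retained genes. Idempotent.
#'
#' @param panel An [ExpressionPanel-class].
#' @param maxMissingPct Allowed missingness per gene in % (default 0).
#' @param excludeGenes Genes excluded a priori (default `"CTNNAL1"`, the
#'   detected-but-uninformative panel member).
#' @return Filtered [ExpressionPanel-class]; the filter report (counts and
#'   reasons) is in `metadata(panel)$inclusion_filter`.
#' @export
applyInclusionFilter <- function(panel, maxMissingPct = 0,
                                 excludeGenes = "CTNNAL1") {
  stopifnot(is(panel, "ExpressionPanel"))
  cc <- completeness(panel)
  dropExplicit <- intersect(rownames(panel), excludeGenes)
  lowGenes <- names(cc)[cc < 100 - maxMissingPct]
  keepGenes <- setdiff(rownames(panel), union(dropExplicit, lowGenes))
  if (length(keepGenes) == 0)
    stop("inclusion filter removed every gene; completeness: ",
         paste(sprintf("%s=%.0f%%", names(cc), cc), collapse = ", "))
  sub <- panel[keepGenes, ]
  keepSamples <- colnames(sub)[colSums(is.na(assay(sub))) == 0]
  if (length(keepSamples) == 0)
    stop("inclusion filter removed every sample")
  out <- sub[, keepSamples]
  # recompute completeness on the retained block
  rowData(out)$completeness <- 100 * rowMeans(!is.na(assay(out)))
  metadata(out)$inclusion_filter <- list(
    genes_in = nrow(panel), genes_out = nrow(out),
    genes_dropped_low_completeness = setdiff(lowGenes, dropExplicit),
    genes_dropped_excluded = dropExplicit,
    samples_in = ncol(panel), samples_out = ncol(out),
    samples_dropped = setdiff(colnames(panel), keepSamples))
  validObject(out)
  out
}

#' Write an ExpressionPanel to disk
#'
#' @param panel An [ExpressionPanel-class].
#' @param dir Output directory; writes `expression_matrix.csv` (wide,
#'   samples x genes), `sample_metadata.csv` and, when present, the filter
#'   report as `inclusion_filter.json`.
#' @return `dir`, invisibly.
#' @export
writeExpressionPanel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- t(assay(panel))
  utils::write.csv(data.frame(sample = rownames(wide), wide,
                              check.names = FALSE),
                   file.path(dir, "expression_matrix.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(colData(panel)),
                   file.path(dir, "sample_metadata.csv"))
  rep <- metadata(panel)$inclusion_filter
  if (!is.null(rep))
    jsonlite::write_json(rep, file.path(dir, "inclusion_filter.json"),
                         auto_unbox = TRUE)
  invisible(dir)
}
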