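# ---------------------------------------------------------------------------
# Chemometric screening core: Pareto preprocessing, NIPALS PCA,
# Hotelling T2 / DModX outlier rejection, OPLS-DA, CV-ANOVA, S-plot
# ---------------------------------------------------------------------------

#' Log10 + Pareto preprocessing
#'
#' Each retained column is transformed as
#' `x' = (log10 x - mean(log10 x)) / sqrt(sd(log10 x))` (Pareto scaling:
#' intermediate between no scaling and unit variance). Zero-variance columns
#' are dropped with a warning. Column means and sd square-roots are stored
#' for the inverse transform and for projecting new samples.
#'
#' @param x Samples x genes matrix of positive relative abundances (no
#'   missing values), or an [ExpressionPanel-class] (transposed internally).
#' @param y Optional class labels aligned with rows; coerced to 0 (control) /
#'   1 (rbst).
#' @return List of class `preprocessedMatrix`: `X` (scaled), `y`, `center`,
#'   `scale` (sqrt sd), `dropped` (zero-variance columns).
#' @export
preprocessPareto <- function(x, y = NULL) {
  if (is(x, "ExpressionPanel")) {
    if (is.null(y)) y <- colData(x)$group
    x <- t(assay(x))
  }
  x <- as.matrix(x)
  if (any(!is.finite(x)))
    stop("missing or non-finite values; apply the inclusion filter first")
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive abundance at sample '", rownames(x)[bad[1, 1]],
         "', gene '", colnames(x)[bad[1, 2]], "'")
  lx <- log10(x)
  sds <- apply(lx, 2, stats::sd)
  dropped <- colnames(lx)[sds == 0]
  if (length(dropped))
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
  keep <- sds > 0
  lx <- lx[, keep, drop = FALSE]
  ctr <- colMeans(lx)
  scl <- sqrt(sds[keep])
  X <- sweep(sweep(lx, 2, ctr), 2, scl, "/")
  yNum <- NULL
  if (!is.null(y)) {
    if (is.character(y) || is.factor(y))
      yNum <- as.numeric(as.character(y) == "rbst")
    else yNum <- as.numeric(y)
    stopifnot(length(yNum) == nrow(X))
  }
  structure(list(X = X, y = yNum, center = ctr, scale = scl,
                 dropped = dropped),
            class = "preprocessedMatrix")
}

#' Invert the log10 + Pareto transform
#'
#' @param pp A `preprocessedMatrix`.
#' @param X Scaled matrix (defaults to `pp$X`).
#' @return Matrix on the original abundance scale.
#' @export
inversePareto <- function(pp, X = pp$X) {
  10^(sweep(sweep(X, 2, pp$scale, "*"), 2, pp$center, "+"))
}

# project new samples (columns matched by name) into an existing preprocessing
.projectPareto <- function(pp, newX) {
  newX <- as.matrix(newX)
  miss <- setdiff(colnames(pp$X), colnames(newX))
  if (length(miss))
    stop("new samples are missing panel gene(s): ",
         paste(miss, collapse = ", "))
  newX <- newX[, colnames(pp$X), drop = FALSE]
  if (any(!is.finite(newX)) || any(newX <= 0))
    stop("new samples must be strictly positive and complete")
  sweep(sweep(log10(newX), 2, pp$center), 2, pp$scale, "/")
}

#' PcaModel: NIPALS principal components
#'
#' @slot scores Samples x A score matrix T.
#' @slot loadings Genes x A orthonormal loading matrix P.
#' @slot r2x Explained fraction of X sum of squares per component.
#' @slot totalSS Total sum of squares of the training matrix.
#' @export
setClass("PcaModel", representation(
  scores = "matrix", loadings = "matrix", r2x = "numeric",
  totalSS = "numeric"))

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel:", ncol(object@scores), "component(s) on",
      nrow(object@scores), "samples\n  R2X:",
      paste(sprintf("%.3f", object@r2x), collapse = ", "),
      "(cum", sprintf("%.3f", sum(object@r2x)), ")\n")
})

#' Fit PCA by NIPALS
#'
#' One component at a time: iterate `p = X't/t't` (normalised), `t = Xp`
#' until the score change is below `tol`, then deflate `X <- X - t p'`.
#' Equivalent to the SVD on complete data; used here for its chemometric
#' conventions (component-wise R2X, natural handling of deflation).
#'
#' @param X Preprocessed samples x genes matrix.
#' @param nComponents Number of components (<= min(dim(X))).
#' @param tol Convergence tolerance on the score change (default 1e-12).
#' @param maxIter Iteration cap per component (default 5000; close
#'   eigenvalues slow the power iteration down).
#' @return A [PcaModel-class].
#' @export
fitPcaNipals <- function(X, nComponents = 2, tol = 1e-12, maxIter = 5000) {
  X <- as.matrix(X)
  .assert(nComponents <= min(dim(X)), "nComponents exceeds matrix rank bound")
  totalSS <- sum(X^2)
  Tm <- matrix(0, nrow(X), nComponents)
  Pm <- matrix(0, ncol(X), nComponents)
  r2x <- numeric(nComponents)
  E <- X
  for (a in seq_len(nComponents)) {
    t <- E[, which.max(apply(E, 2, stats::var)), drop = TRUE]
    if (all(t == 0)) t <- E[, 1]
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      p <- drop(crossprod(E, t)) / sum(t^2)
      p <- p / sqrt(sum(p^2))
      tNew <- drop(E %*% p)
      if (sqrt(sum((tNew - t)^2)) < tol * max(sqrt(sum(tNew^2)), 1)) {
        t <- tNew; converged <- TRUE; break
      }
      t <- tNew
    }
    if (!converged)
      stop("NIPALS did not converge for component ", a)
    E <- E - tcrossprod(t, p)
    Tm[, a] <- t; Pm[, a] <- p
    r2x[a] <- sum(t^2) / totalSS   # p orthonormal: SS removed = t't
  }
  dimnames(Tm) <- list(rownames(X), paste0("PC", seq_len(nComponents)))
  dimnames(Pm) <- list(colnames(X), colnames(Tm))
  new("PcaModel", scores = Tm, loadings = Pm, r2x = r2x, totalSS = totalSS)
}

#' Hotelling's T2 and its F-based limit
#'
#' `T2_i = sum_a t_ia^2 / var(t_a)`; the `(N^2-1)` limit variant common in
#' chemometrics software is
#' `A (N-1)(N+1) / (N (N-A)) * F_{1-alpha}(A, N-A)`; the `(N-1)` variant is
#' available by flag.
#'
#' @param model A [PcaModel-class].
#' @param alpha Significance level (default 0.05).
#' @param variant `"n2"` (default) or `"n1"`.
#' @return List with `t2` (per sample) and `limit`.
#' @export
hotellingT2 <- function(model, alpha = 0.05, variant = c("n2", "n1")) {
  variant <- match.arg(variant)
  Tm <- model@scores
  N <- nrow(Tm); A <- ncol(Tm)
  .assert(N > A, "need more samples than components")
  v <- apply(Tm, 2, stats::var)
  t2 <- rowSums(sweep(Tm^2, 2, v, "/"))
  fq <- stats::qf(1 - alpha, A, N - A)
  limit <- if (variant == "n2") A * (N - 1) * (N + 1) / (N * (N - A)) * fq
  else A * (N - 1) / (N - A) * fq
  list(t2 = t2, limit = limit)
}

#' Distance to the model in X space (DModX)
#'
#' `DModX_i = sqrt(RSS_i / (K - A))`, normalised by the pooled residual sd
#' `s0 = sqrt(sum RSS / ((N - A - 1)(K - A)))`; the critical limit is the
#' square root of the `F_{1-alpha}(K - A, (N - A - 1)(K - A))` quantile.
#'
#' @param X The matrix the model was fitted on.
#' @param model A [PcaModel-class].
#' @param alpha Significance level.
#' @return List with `dmodx` (normalised), `s0`, `limit`.
#' @export
dmodx <- function(X, model, alpha = 0.05) {
  X <- as.matrix(X)
  N <- nrow(X); K <- ncol(X); A <- ncol(model@scores)
  .assert(K > A, "need more variables than components")
  E <- X - tcrossprod(model@scores, model@loadings)
  rss <- rowSums(E^2)
  s0 <- sqrt(sum(rss) / ((N - A - 1) * (K - A)))
  d <- sqrt(rss / (K - A)) / s0
  limit <- sqrt(stats::qf(1 - alpha, K - A, (N - A - 1) * (K - A)))
  list(dmodx = d, s0 = s0, limit = limit)
}

#' Flag multivariate outliers (single pass)
#'
#' A sample is excluded when it exceeds the Hotelling T2 95% limit or the
#' DModX critical limit. Exclusion is applied once (no iterative refitting).
#'
#' @param X Preprocessed matrix.
#' @param model [PcaModel-class] fitted on `X`.
#' @param alpha Significance level for both limits.
#' @return List with `excluded` (names), `reason` (per excluded sample),
#'   `t2`, `dmodx` reports.
#' @export
flagOutliers <- function(X, model, alpha = 0.05) {
  h <- hotellingT2(model, alpha = alpha)
  d <- dmodx(X, model, alpha = alpha)
  overT <- h$t2 > h$limit
  overD <- d$dmodx > d$limit
  ex <- overT | overD
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  reason <- ifelse(overT & overD, "t2+dmodx",
                   ifelse(overT, "t2", "dmodx"))[ex]
  list(excluded = ids[ex], reason = stats::setNames(reason, ids[ex]),
       t2 = h, dmodx = d)
}

#' OplsdaModel: OPLS discriminant model
#'
#' @slot weights Predictive weight vector w.
#' @slot scores Predictive score vector t.
#' @slot loadings Predictive loading vector p.
#' @slot orthoWeights,orthoScores,orthoLoadings Orthogonal component sets
#'   (genes x nOrth, samples x nOrth, genes x nOrth).
#' @slot b Inner regression coefficient.
#' @slot yMean Training-class mean of y.
#' @slot r2x,r2y,q2 Explained X / explained Y / cross-validated Y fractions.
#' @slot nOrth Number of orthogonal components.
#' @slot uninformative TRUE when X carries (numerically) no y covariance.
#' @export
setClass("OplsdaModel", representation(
  weights = "numeric", scores = "numeric", loadings = "numeric",
  orthoWeights = "matrix", orthoScores = "matrix", orthoLoadings = "matrix",
  b = "numeric", yMean = "numeric", r2x = "numeric", r2y = "numeric",
  q2 = "numeric", nOrth = "integer", uninformative = "logical"))

setMethod("show", "OplsdaModel", function(object) {
  cat("OplsdaModel: 1 predictive +", object@nOrth,
      "orthogonal component(s)\n",
      sprintf("  R2X = %.3f, R2Y = %.3f, Q2 = %.3f\n",
              object@r2x, object@r2y, object@q2))
  if (object@uninformative) cat("  flagged uninformative (no y covariance)\n")
})

# one O-PLS pass with a fixed number of orthogonal components; y centred
.oplsCore <- function(X, yc, nOrth) {
  K <- ncol(X)
  Wo <- matrix(0, K, nOrth); Po <- matrix(0, K, nOrth)
  To <- matrix(0, nrow(X), nOrth)
  E <- X
  uninformative <- FALSE
  for (k in seq_len(max(nOrth, 0L))) {
    w <- drop(crossprod(E, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { uninformative <- TRUE; break }
    w <- w / nw
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(E %*% wo)
    po <- drop(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    Wo[, k] <- wo; Po[, k] <- po; To[, k] <- to
  }
  w <- drop(crossprod(E, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) {
    uninformative <- TRUE
    w <- rep(0, K); t <- rep(0, nrow(X)); p <- rep(0, K); b <- 0
  } else {
    w <- w / nw
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    b <- sum(t * yc) / sum(t^2)
  }
  list(w = w, t = t, p = p, Wo = Wo, Po = Po, To = To, b = b,
       uninformative = uninformative)
}

# predict centred y for new preprocessed rows
.oplsPredict <- function(core, newX, yMean) {
  E <- as.matrix(newX)
  nOrth <- ncol(core$Wo)
  for (k in seq_len(max(nOrth, 0L))) {
    if (all(core$Wo[, k] == 0)) next
    to <- drop(E %*% core$Wo[, k])
    E <- E - tcrossprod(to, core$Po[, k])
  }
  t <- drop(E %*% core$w)
  list(yhat = yMean + core$b * t, t = t)
}

#' Fit an OPLS-DA model
#'
#' The O-PLS algorithm: the predictive weight is `w ~ X'y` (normalised);
#' each orthogonal component is extracted from the part of the loading
#' orthogonal to `w`, and X is deflated by it. By default orthogonal
#' components are added while the 7-fold cross-validated Q2 improves by more
#' than `q2Gain` (max `maxOrth`); `nOrth` can also be fixed. The predictive
#' score is oriented so the treated-class mean is positive.
#'
#' @param X Preprocessed samples x genes matrix (or `preprocessedMatrix`).
#' @param y Binary class vector (0 = control, 1 = rbst); taken from the
#'   `preprocessedMatrix` if absent.
#' @param nOrth `"auto"` (default) or a fixed count.
#' @param folds Cross-validation folds for the auto rule and for `q2`.
#' @param q2Gain Minimum Q2 improvement to accept another orthogonal
#'   component.
#' @param maxOrth Cap on orthogonal components.
#' @return An [OplsdaModel-class].
#' @export
fitOplsda <- function(X, y = NULL, nOrth = "auto", folds = 7,
                      q2Gain = 0.01, maxOrth = 3) {
  if (inherits(X, "preprocessedMatrix")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as.matrix(X); y <- as.numeric(y)
  .assert(length(unique(y)) == 2, "y must contain exactly two classes")
  .assert(min(table(y)) >= 3, "need >= 3 samples per class")
  yc <- y - mean(y)

  if (identical(nOrth, "auto")) {
    best <- 0L
    q2Best <- crossValidateQ2(X, y, folds = folds, nOrth = 0L)
    for (k in seq_len(maxOrth)) {
      q2k <- crossValidateQ2(X, y, folds = folds, nOrth = k)
      if (q2k > q2Best + q2Gain) { best <- k; q2Best <- q2k } else break
    }
    nOrth <- best
    q2 <- q2Best
  } else {
    nOrth <- as.integer(nOrth)
    q2 <- crossValidateQ2(X, y, folds = folds, nOrth = nOrth)
  }

  core <- .oplsCore(X, yc, nOrth)
  # orient: treated-class mean score positive
  if (!core$uninformative && mean(core$t[y == 1]) < mean(core$t[y == 0])) {
    core$w <- -core$w; core$t <- -core$t; core$p <- -core$p
    core$b <- -core$b
  }
  yhat <- mean(y) + core$b * core$t
  r2y <- 1 - sum((y - yhat)^2) / sum(yc^2)
  ssx <- sum(X^2)
  ssExplained <- sum(core$t^2 * sum(core$p^2))
  if (nOrth > 0)
    ssExplained <- ssExplained +
      sum(vapply(seq_len(nOrth), function(k)
        sum(core$To[, k]^2) * sum(core$Po[, k]^2), numeric(1)))
  new("OplsdaModel",
      weights = core$w, scores = core$t, loadings = core$p,
      orthoWeights = core$Wo, orthoScores = core$To, orthoLoadings = core$Po,
      b = core$b, yMean = mean(y),
      r2x = min(1, ssExplained / ssx), r2y = max(0, r2y), q2 = q2,
      nOrth = as.integer(nOrth), uninformative = core$uninformative)
}

# deterministic round-robin fold assignment over samples sorted by id
.cvFolds <- function(ids, folds) {
  ord <- order(ids)
  fold <- integer(length(ids))
  fold[ord] <- rep_len(seq_len(folds), length(ids))
  fold
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Deterministic 7-fold assignment (samples sorted by id, round-robin); each
#' fold's samples are predicted from a model refitted on the rest.
#' `Q2 = 1 - PRESS / SS(y - mean(y))`.
#'
#' @param X Preprocessed matrix.
#' @param y Binary class vector.
#' @param folds Number of folds (>= 2, <= N).
#' @param nOrth Orthogonal components used in each refit.
#' @return Q2 (scalar). Attributes `press` and `press0` (PRESS of the
#'   training-fold-mean-only model) support CV-ANOVA.
#' @export
crossValidateQ2 <- function(X, y, folds = 7, nOrth = 0L) {
  X <- as.matrix(X); y <- as.numeric(y)
  .assert(folds >= 2, "folds must be >= 2 (Q2 on training data is R2Y)")
  .assert(nrow(X) >= folds, "more folds than samples")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("s%06d", seq_len(nrow(X)))
  fold <- .cvFolds(ids, folds)
  press <- 0; press0 <- 0
  for (f in seq_len(folds)) {
    test <- fold == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2)
      stop("a training fold lost one class entirely; use fewer folds")
    core <- .oplsCore(X[!test, , drop = FALSE], ytr - mean(ytr), nOrth)
    pred <- .oplsPredict(core, X[test, , drop = FALSE], mean(ytr))
    press <- press + sum((y[test] - pred$yhat)^2)
    press0 <- press0 + sum((y[test] - mean(ytr))^2)
  }
  q2 <- 1 - press / sum((y - mean(y))^2)
  attr(q2, "press") <- press
  attr(q2, "press0") <- press0
  attr(q2, "nOrth") <- nOrth
  q2
}

#' CV-ANOVA significance of an OPLS-DA model
#'
#' Compares the cross-validated predictive residuals of the model against
#' those of the trivial (training-fold mean only) model:
#' `F = ((PRESS0 - PRESS) / d1) / (PRESS / d2)` with `d1 = A` (fitted
#' components, predictive + orthogonal) and `d2 = N - 1 - A`, p from the F
#' distribution. A model no better than the mean gives F truncated at 0 and
#' p = 1.
#'
#' @param X Preprocessed matrix.
#' @param y Binary class vector.
#' @param nOrth Orthogonal components (e.g. from a fitted model).
#' @param folds CV folds.
#' @return Data frame `F`, `df1`, `df2`, `p`, `press`, `press0`.
#' @export
cvAnova <- function(X, y, nOrth = 0L, folds = 7) {
  q2 <- crossValidateQ2(X, y, folds = folds, nOrth = nOrth)
  press <- attr(q2, "press"); press0 <- attr(q2, "press0")
  A <- 1L + as.integer(nOrth)
  N <- nrow(as.matrix(X))
  d1 <- A; d2 <- N - 1L - A
  F <- ((press0 - press) / d1) / (press / d2)
  if (!is.finite(F) || F < 0) F <- 0
  p <- stats::pf(F, d1, d2, lower.tail = FALSE)
  data.frame(F = F, df1 = d1, df2 = d2, p = p,
             press = press, press0 = press0)
}

#' S-plot coordinates
#'
#' For each gene: `p1 = cov(t, x_g) = t'x_g / (N - 1)` (model units) and
#' `pcorr1 = p1 / (sd(t) sd(x_g))` (correlation, in \[-1, 1\]). With the
#' score oriented treated-positive, genes up-regulated under treatment sit in
#' the upper-right corner.
#'
#' @param model An [OplsdaModel-class].
#' @param X The preprocessed matrix the model was fitted on.
#' @return Data frame `gene`, `p1`, `pcorr1`, `flag` (`"ok"` or
#'   `"zero_variance"`).
#' @export
sPlot <- function(model, X) {
  X <- as.matrix(X)
  t <- model@scores
  N <- nrow(X)
  p1 <- drop(crossprod(X, t)) / (N - 1)
  sdx <- apply(X, 2, stats::sd)
  sdt <- stats::sd(t)
  pcorr <- ifelse(sdx > 0 & sdt > 0, p1 / (sdt * sdx), NA_real_)
  data.frame(gene = colnames(X), p1 = p1, pcorr1 = pcorr,
             flag = ifelse(sdx > 0, "ok", "zero_variance"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank biomarker candidates from an S-plot
#'
#' Genes ordered by |pcorr1| descending (ties by |p1|); the panel comprises
#' genes with |pcorr1| above the threshold.
#'
#' @param splot Data frame from [sPlot()].
#' @param threshold |pcorr1| cutoff for panel membership (default 0.4).
#' @return Data frame ordered by rank with a logical `in_panel` column.
#' @export
rankBiomarkers <- function(splot, threshold = 0.4) {
  s <- splot[order(-abs(splot$pcorr1), -abs(splot$p1)), ]
  s$rank <- seq_len(nrow(s))
  s$in_panel <- !is.na(s$pcorr1) & abs(s$pcorr1) > threshold
  rownames(s) <- NULL
  s
}
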