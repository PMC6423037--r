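# ---------------------------------------------------------------------------
# Multiplicative between-session (between-run) factor correction
# ---------------------------------------------------------------------------

#' Between-session ratio matrix
#'
#' Entry (i, j) is the geometric mean, over conditions measured in both
#' sessions, of the ratio of the condition mean in session i to the condition
#' mean in session j. The default condition key is gene x group. The support
#' count per entry is returned alongside.
#'
#' @param n0 Data frame with a positive `value` column (N0), a `session`
#'   column, and the condition columns.
#' @param conditionKey Character vector of column names defining a shared
#'   condition (default `c("gene", "group")`).
#' @param value Name of the value column (default `"N0"`, falling back to
#'   `"value"`).
#' @return List with `ratio` (square matrix over sessions), `support` (counts
#'   of shared conditions) and `conditionMeans` (long data frame).
#' @export
betweenSessionRatioMatrix <- function(n0, conditionKey = c("gene", "group"),
                                      value = if ("N0" %in% names(n0)) "N0"
                                      else "value") {
  .assert(all(c(conditionKey, "session", value) %in% names(n0)),
          "n0 must contain session, value and condition-key columns")
  v <- n0[[value]]
  keep <- !is.na(v) & v > 0
  n0 <- n0[keep, ]; v <- v[keep]
  cond <- interaction(n0[conditionKey], drop = TRUE, sep = ":")
  sess <- factor(n0$session)
  # condition-by-session matrix of (arithmetic) condition means, log scale
  means <- tapply(v, list(cond, sess), mean)
  lm <- log(means)
  S <- nlevels(sess)
  ratio <- matrix(NA_real_, S, S, dimnames = list(levels(sess), levels(sess)))
  support <- matrix(0L, S, S, dimnames = dimnames(ratio))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    shared <- which(!is.na(lm[, i]) & !is.na(lm[, j]))
    support[i, j] <- length(shared)
    if (length(shared))
      ratio[i, j] <- exp(mean(lm[shared, i] - lm[shared, j]))
  }
  # connectivity check
  adj <- support > 0
  comp <- .connectedComponents(adj)
  if (max(comp) > 1L) {
    grpList <- split(levels(sess), comp)
    stop("session graph is disconnected; unbridgeable session sets: ",
         paste(vapply(grpList, paste, "", collapse = ","), collapse = " | "))
  }
  cm <- as.data.frame(as.table(means), stringsAsFactors = FALSE)
  names(cm) <- c("condition", "session", "mean")
  list(ratio = ratio, support = support, conditionMeans = cm[!is.na(cm$mean), ])
}

.connectedComponents <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n); k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Estimate multiplicative session factors
#'
#' Default estimator: the factor of session i is the geometric mean over j of
#' ratio(i, j), renormalised so the factors have geometric mean 1 (corrected
#' data stay on the original scale on average). The `"ml"` estimator maximises
#' the log-normal likelihood of the observed condition means under
#' multiplicative session effects, by alternating updates of condition and
#' session effects until the largest factor change is below `tol`.
#'
#' @param ratios Result of [betweenSessionRatioMatrix()].
#' @param method `"geometric"` (default) or `"ml"`.
#' @param tol,maxIter Convergence controls for `"ml"`.
#' @return Named numeric vector of factors (geometric mean 1).
#' @export
estimateSessionFactors <- function(ratios, method = c("geometric", "ml"),
                                   tol = 1e-10, maxIter = 500) {
  method <- match.arg(method)
  R <- ratios$ratio
  if (method == "geometric") {
    lf <- apply(log(R), 1, mean, na.rm = TRUE)
  } else {
    cm <- ratios$conditionMeans
    y <- log(cm$mean)
    condF <- factor(cm$condition); sessF <- factor(cm$session,
                                                   levels = rownames(R))
    mu <- tapply(y, condF, mean)[condF]
    phi <- stats::setNames(rep(0, nlevels(sessF)), levels(sessF))
    for (it in seq_len(maxIter)) {
      phiNew <- tapply(y - mu, sessF, mean)
      phiNew[is.na(phiNew)] <- 0
      phiNew <- phiNew - mean(phiNew)
      mu <- tapply(y - phiNew[sessF], condF, mean)[condF]
      delta <- max(abs(phiNew - phi))
      phi <- phiNew
      if (delta < tol) break
    }
    if (delta >= tol)
      stop("ML session-factor estimation did not converge; last factors: ",
           paste(signif(exp(phi), 6), collapse = ", "))
    lf <- stats::setNames(as.numeric(phi), levels(sessF))[rownames(R)]
  }
  lf <- lf - mean(lf)
  stats::setNames(exp(lf), rownames(R))
}

#' Divide observed values by their session factor
#'
#' Non-idempotent by construction: applying the correction twice divides
#' twice.
#'
#' @param n0 Data frame with `session` and a value column.
#' @param factors Named factor vector from [estimateSessionFactors()].
#' @param value Value column name (default `"N0"`/`"value"` as available).
#' @return `n0` with the value column divided by the session factor and a
#'   provenance column `session_factor`.
#' @export
applySessionFactors <- function(n0, factors,
                                value = if ("N0" %in% names(n0)) "N0"
                                else "value") {
  .assert("session" %in% names(n0), "n0 needs a session column")
  miss <- setdiff(unique(as.character(n0$session)), names(factors))
  if (length(miss))
    stop("no factor for session(s): ", paste(miss, collapse = ", "))
  f <- factors[as.character(n0$session)]
  n0[[value]] <- n0[[value]] / f
  n0$session_factor <- unname(f)
  n0
}

#' Write session factors as CSV
#'
#' @param factors Named factor vector.
#' @param ratios Optional [betweenSessionRatioMatrix()] result for support
#'   counts.
#' @param path Output CSV (`session`, `factor`, `n_conditions`).
#' @return `path`, invisibly.
#' @export
writeSessionFactors <- function(factors, path, ratios = NULL) {
  n <- if (is.null(ratios)) NA_integer_ else diag(ratios$support)
  utils::write.csv(data.frame(session = names(factors),
                              factor = unname(factors),
                              n_conditions = n),
                   path, row.names = FALSE)
  invisible(path)
}
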