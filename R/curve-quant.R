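# ---------------------------------------------------------------------------
# Amplification-curve quantification: baseline, window of linearity,
# efficiency, Cq and starting concentration N0
# ---------------------------------------------------------------------------

# Window score for a matrix of candidate baselines.
# FM: (grid x cycles) baseline-corrected fluorescence. For each row, candidate
# windows of 4-6 consecutive cycles must lie above the noise floor and below
# upperFrac of the plateau (max F'); the 5% default keeps the window in the
# early exponential phase, where the logistic's per-cycle ratio is still the
# true efficiency. Among windows whose log-linear r2 is within r2Tol of the
# row maximum, the steepest window is chosen: plateau bending only ever
# flattens the log-slope, so the steepest near-tied window is the one inside
# the exponential phase. Exact ties go to the later window, then the longer
# one.
.bestWindowMatrix <- function(FM, noiseFloor, lengths = 4:6, r2Tol = 0.002,
                              upperFrac = 0.05) {
  G <- nrow(FM); C <- ncol(FM)
  plateau <- .rowMax(FM)
  valid <- FM > pmax(noiseFloor, 0) & FM < upperFrac * plateau
  Y <- ifelse(valid, log10(pmax(FM, .Machine$double.xmin)), 0)
  V <- valid * 1
  cyc <- seq_len(C)
  Yx <- sweep(Y, 2, cyc, "*")
  Y2 <- Y * Y
  r2All <- NULL; slopeAll <- NULL; firstAll <- integer(0); lastAll <- integer(0)
  for (L in lengths) {
    nw <- C - L + 1L
    if (nw < 1L) next
    W <- matrix(0, C, nw)
    for (s in seq_len(nw)) W[s:(s + L - 1L), s] <- 1
    ok <- (V %*% W) == L
    Sy <- Y %*% W; Syy <- Y2 %*% W; Sxy <- Yx %*% W
    starts <- seq_len(nw)
    Sx <- vapply(starts, function(s) sum(s:(s + L - 1L)), numeric(1))
    Sxx <- vapply(starts, function(s) sum((s:(s + L - 1L))^2), numeric(1))
    den1 <- L * Sxx - Sx^2                     # per-window, x part
    den2 <- L * Syy - Sy^2                     # per-row-and-window, y part
    num <- L * Sxy - sweep(Sy, 2, Sx, "*")
    slope <- sweep(num, 2, den1, "/")
    r2 <- num^2 / sweep(pmax(den2, .Machine$double.xmin), 2, den1, "*")
    bad <- !ok | !is.finite(r2) | num <= 0     # must be a rising phase
    r2[bad] <- -Inf; slope[bad] <- -Inf
    r2All <- cbind(r2All, r2)
    slopeAll <- cbind(slopeAll, slope)
    firstAll <- c(firstAll, starts)
    lastAll <- c(lastAll, starts + L - 1L)
  }
  maxR2 <- .rowMax(r2All)
  eligible <- sweep(r2All, 1, maxR2 - r2Tol, ">=") & is.finite(r2All)
  # composite key: slope first, then later window, then longer window
  key <- slopeAll + outer(rep(1, G), lastAll) * 1e-9 +
    outer(rep(1, G), lastAll - firstAll) * 1e-12
  key[!eligible] <- -Inf
  pick <- max.col(key, ties.method = "last")
  found <- is.finite(maxR2)
  list(r2 = ifelse(found, r2All[cbind(seq_len(G), pick)], -Inf),
       first = ifelse(found, firstAll[pick], NA_integer_),
       last = ifelse(found, lastAll[pick], NA_integer_),
       slope = ifelse(found, slopeAll[cbind(seq_len(G), pick)], NA_real_))
}

# rowMax without extra dependencies
.rowMax <- function(m) do.call(pmax, as.data.frame(m))

#' Baseline-correct one amplification curve
#'
#' The constant baseline is first estimated as the mean of the
#' pre-amplification cycles (cycles before the fluorescence climbs past the
#' early-cycle noise band) and then refined by grid search (201 points by
#' default) within that estimate's uncertainty, maximising the r-squared of
#' the best log-linear window of the corrected series. Anchoring the search
#' on the pre-amplification cycles keeps the refinement well-posed: an
#' unconstrained baseline can always straighten some short window and biases
#' the efficiency. A curve whose corrected rise does not exceed three times
#' the early-cycle noise sd is flagged `no_amplification` and gets the series
#' median as baseline.
#'
#' @param fluorescence Numeric vector over cycles 1..C (C >= 10).
#' @param gridPoints Number of candidate baselines in the refinement.
#' @return List with `baseline`, `corrected`, `flag` (`"ok"`,
#'   `"no_amplification"` or `"poor_fit"`), `window` (`c(first, last)` or
#'   `NULL`) and `r2` of the best window.
#' @export
correctBaseline <- function(fluorescence, gridPoints = 201) {
  f <- as.numeric(fluorescence)
  .assert(length(f) >= 10 && all(is.finite(f)),
          "need >= 10 finite fluorescence values")
  early <- f[1:5]
  noiseSd <- stats::sd(early)
  rise <- max(f) - stats::median(early)
  if (rise <= 3 * noiseSd || rise <= 0) {
    return(list(baseline = stats::median(f), corrected = f - stats::median(f),
                flag = "no_amplification", window = NULL, r2 = NA_real_))
  }
  # pre-amplification stretch: cycles before the curve leaves the noise band
  thr <- stats::median(early) + 3 * noiseSd
  above <- which(f > thr)
  onset <- if (length(above)) min(above) else length(f)
  nBase <- max(3L, onset - 3L)
  b0 <- mean(f[seq_len(nBase)])
  # refine within ~2 standard errors of the pre-amplification mean
  spread <- max(stats::sd(f[seq_len(nBase)]) / sqrt(nBase), b0 * 1e-9, 1e-12)
  lo <- max(0, b0 - 2 * spread)
  hi <- max(lo, b0 + 2 * spread)
  grid <- if (hi > lo) seq(lo, hi, length.out = gridPoints) else lo
  FM <- outer(rep(1, length(grid)), f) - grid
  bw <- .bestWindowMatrix(FM, noiseFloor = 3 * noiseSd)
  if (all(!is.finite(bw$r2))) {
    return(list(baseline = stats::median(f), corrected = f - stats::median(f),
                flag = "poor_fit", window = NULL, r2 = NA_real_))
  }
  i <- which.max(bw$r2)
  list(baseline = grid[i], corrected = f - grid[i], flag = "ok",
       window = c(bw$first[i], bw$last[i]), r2 = bw$r2[i])
}

#' Find the window of linearity of a baseline-corrected curve
#'
#' Among candidate windows of 4--6 consecutive cycles whose corrected
#' fluorescence lies above the noise floor (3 x sd of the first five corrected
#' cycles) and inside the early exponential phase (below 5% of the plateau,
#' where the per-cycle ratio is undistorted), returns the window maximising
#' the r-squared of `log10 F'` on cycle, preferring the steepest among
#' near-tied candidates; exact ties go to the later (higher fluorescence)
#' window.
#'
#' @param corrected Baseline-corrected fluorescence vector.
#' @return List with `window = c(first, last)` and `r2`, or `NULL` when no
#'   candidate window exists (poor fit).
#' @export
findWindowOfLinearity <- function(corrected) {
  f <- as.numeric(corrected)
  noiseSd <- stats::sd(f[1:5])
  bw <- .bestWindowMatrix(matrix(f, nrow = 1), noiseFloor = 3 * noiseSd)
  if (!is.finite(bw$r2[1])) return(NULL)
  list(window = c(bw$first[1], bw$last[1]), r2 = bw$r2[1])
}

#' Per-sample amplification efficiency from the window of linearity
#'
#' Ordinary least squares of `log10 F'` on cycle inside the window; the
#' efficiency is `10^slope` (fold amplification per cycle).
#'
#' @param corrected Baseline-corrected fluorescence vector.
#' @param window `c(first, last)` cycle indices, length 4--6.
#' @return List with `efficiency`, `r2`, `slope`, `intercept`.
#' @export
fitSampleEfficiency <- function(corrected, window) {
  .assert(length(window) == 2 && diff(window) >= 3,
          "window must span at least 4 cycles (poor_fit)")
  cyc <- window[1]:window[2]
  y <- log10(corrected[cyc])
  .assert(all(is.finite(y)), "non-positive corrected fluorescence in window")
  fit <- stats::lm.fit(cbind(1, cyc), y)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  if (!is.finite(r2)) r2 <- 1  # zero-variance y cannot occur for slope > 0
  list(efficiency = unname(10^slope), r2 = r2,
       slope = unname(slope), intercept = unname(fit$coefficients[1]))
}

#' Mean amplicon efficiency across wells
#'
#' Per-sample efficiencies more than `maxDev` from the amplicon median, or
#' with a non-`ok` flag, are excluded; the mean is taken over the remainder.
#'
#' @param efficiency Numeric vector of per-well efficiencies for one amplicon.
#' @param flags Character vector of per-well flags (`"ok"` to include).
#' @param maxDev Maximum allowed |E - median(E)| (default 0.05).
#' @return List with `meanEfficiency`, `sdEfficiency`, `nUsed`, `nExcluded`,
#'   `used` (logical vector).
#' @export
summarizeAmpliconEfficiency <- function(efficiency,
                                        flags = rep("ok", length(efficiency)),
                                        maxDev = 0.05) {
  .assert(length(efficiency) >= 1, "no fits supplied for amplicon")
  ok <- flags == "ok" & is.finite(efficiency)
  .assert(any(ok), "no ok fits for amplicon: unquantifiable")
  med <- stats::median(efficiency[ok])
  used <- ok & abs(efficiency - med) <= maxDev
  .assert(any(used), "all efficiencies excluded as outliers: unquantifiable")
  list(meanEfficiency = mean(efficiency[used]),
       sdEfficiency = stats::sd(efficiency[used]),
       nUsed = sum(used), nExcluded = sum(!used), used = used)
}

#' Quantify a set of amplification curves
#'
#' Runs the full per-well chain (baseline correction, window of linearity,
#' per-sample efficiency), summarises the mean efficiency per amplicon, sets
#' one quantification threshold Nq per amplicon (the geometric mean of the
#' window-midpoint fitted fluorescences over that amplicon's `ok` wells), and
#' computes `Cq` (fractional cycle where the fitted log-linear segment crosses
#' Nq) and `N0 = Nq / meanE^Cq` for every `ok` well. Wells whose Cq falls more
#' than one cycle outside their window are flagged `poor_fit`
#' (extrapolation).
#'
#' @param curves Long-format data frame with columns `well`, `gene`, `cycle`,
#'   `fluorescence` (extra metadata columns `sample`, `animal`, `group`,
#'   `day`, `session`, `replicate` are carried through when present).
#' @param gridPoints Baseline grid size, see [correctBaseline()].
#' @param maxEffDev Efficiency-outlier cutoff, see
#'   [summarizeAmpliconEfficiency()].
#' @return List with `fits` (per-well data frame: baseline, window,
#'   efficiency, r2, flag, Cq, Nq, N0) and `amplicons` (per-gene data frame:
#'   meanEfficiency, sdEfficiency, nUsed, nExcluded, Nq).
#' @export
quantifyCurves <- function(curves, gridPoints = 201, maxEffDev = 0.05) {
  need <- c("well", "gene", "cycle", "fluorescence")
  .assert(all(need %in% names(curves)),
          paste("curves must have columns:", paste(need, collapse = ", ")))
  meta <- intersect(c("sample", "animal", "group", "day", "session",
                      "replicate"), names(curves))
  curves <- curves[order(curves$well, curves$cycle), ]
  idx <- split(seq_len(nrow(curves)), curves$well)
  wells <- names(idx)

  fitOne <- function(i) {
    f <- curves$fluorescence[i]
    cb <- correctBaseline(f, gridPoints = gridPoints)
    out <- list(baseline = cb$baseline, flag = cb$flag,
                windowFirst = NA_integer_, windowLast = NA_integer_,
                efficiency = NA_real_, r2 = NA_real_,
                slope = NA_real_, intercept = NA_real_, midFluor = NA_real_)
    if (cb$flag == "ok") {
      fe <- fitSampleEfficiency(cb$corrected, cb$window)
      mid <- mean(cb$window)
      out$windowFirst <- cb$window[1]; out$windowLast <- cb$window[2]
      out$efficiency <- fe$efficiency; out$r2 <- fe$r2
      out$slope <- fe$slope; out$intercept <- fe$intercept
      out$midFluor <- 10^(fe$intercept + fe$slope * mid)
    }
    out
  }
  per <- lapply(idx, fitOne)
  fits <- data.frame(well = wells, stringsAsFactors = FALSE)
  firstRow <- vapply(idx, function(v) v[1], integer(1))
  for (m in c("gene", meta)) fits[[m]] <- curves[[m]][firstRow]
  for (col in names(per[[1]]))
    fits[[col]] <- unlist(lapply(per, `[[`, col), use.names = FALSE)

  # per-amplicon mean efficiency and common quantification threshold; an
  # amplicon with no quantifiable well (e.g. a never-expressed gene, all
  # wells flat) is reported with NA statistics rather than aborting the run
  amp <- lapply(split(seq_len(nrow(fits)), fits$gene), function(j) {
    s <- tryCatch(
      summarizeAmpliconEfficiency(fits$efficiency[j], fits$flag[j],
                                  maxDev = maxEffDev),
      error = function(e) list(meanEfficiency = NA_real_,
                               sdEfficiency = NA_real_, nUsed = 0L,
                               nExcluded = length(j),
                               used = rep(FALSE, length(j))))
    okj <- j[fits$flag[j] == "ok"]
    list(rows = j, used = s$used,
         meanEfficiency = s$meanEfficiency, sdEfficiency = s$sdEfficiency,
         nUsed = s$nUsed, nExcluded = s$nExcluded,
         Nq = if (length(okj)) geomMean(fits$midFluor[okj]) else NA_real_)
  })
  amplicons <- data.frame(
    gene = names(amp),
    meanEfficiency = vapply(amp, `[[`, numeric(1), "meanEfficiency"),
    sdEfficiency = vapply(amp, `[[`, numeric(1), "sdEfficiency"),
    nUsed = vapply(amp, `[[`, numeric(1), "nUsed"),
    nExcluded = vapply(amp, `[[`, numeric(1), "nExcluded"),
    Nq = vapply(amp, `[[`, numeric(1), "Nq"),
    row.names = NULL, stringsAsFactors = FALSE)

  # flag efficiency outliers (kept out of the mean but still quantified)
  for (a in amp) {
    out <- a$rows[fits$flag[a$rows] == "ok" & !a$used]
    if (length(out)) fits$flag[out] <- "efficiency_outlier"
  }

  n0 <- quantifyN0(fits, amplicons)
  fits$Nq <- n0$Nq; fits$Cq <- n0$Cq; fits$N0 <- n0$N0
  fits$flag <- n0$flag
  list(fits = fits, amplicons = amplicons)
}

#' Compute Cq and N0 for fitted wells
#'
#' Given per-well log-linear fits and per-amplicon summaries (mean efficiency
#' and common threshold Nq), computes `Cq = (log10 Nq - intercept)/slope` and
#' `N0 = Nq / meanE^Cq` so that `N0 * meanE^Cq = Nq` holds exactly. Wells
#' whose crossing lies more than `extrapolation` cycles outside their own
#' window are flagged `poor_fit`; the default of 3 cycles accommodates the
#' legitimate spread of window positions across wells (starting-material and
#' session-scale differences shift each well's window) while rejecting
#' crossings far outside the fitted log-linear phase.
#'
#' @param fits Per-well data frame (needs `gene`, `flag`, `slope`,
#'   `intercept`, `windowFirst`, `windowLast`).
#' @param amplicons Per-gene data frame (needs `gene`, `meanEfficiency`,
#'   `Nq`).
#' @param extrapolation Allowed overshoot in cycles (default 3).
#' @return List of vectors `Nq`, `Cq`, `N0`, `flag` aligned with `fits`.
#' @export
quantifyN0 <- function(fits, amplicons, extrapolation = 3) {
  m <- match(fits$gene, amplicons$gene)
  Nq <- amplicons$Nq[m]
  meanE <- amplicons$meanEfficiency[m]
  # efficiency outliers are excluded from the amplicon mean but keep their
  # own log-linear fit and are still quantified against the common threshold
  ok <- fits$flag %in% c("ok", "efficiency_outlier")
  Cq <- ifelse(ok, (log10(Nq) - fits$intercept) / fits$slope, NA_real_)
  flag <- fits$flag
  extra <- ok & (Cq < fits$windowFirst - extrapolation |
                   Cq > fits$windowLast + extrapolation)
  flag[extra] <- "poor_fit"
  usable <- flag %in% c("ok", "efficiency_outlier")
  N0 <- ifelse(usable, Nq / meanE^Cq, NA_real_)
  Cq[!usable] <- NA_real_
  list(Nq = ifelse(usable, Nq, NA_real_), Cq = Cq, N0 = N0, flag = flag)
}

#' Write per-well fits and per-amplicon summaries
#'
#' @param quant Result of [quantifyCurves()].
#' @param dir Output directory; writes `well_fits.csv` and
#'   `amplicon_summary.csv`.
#' @return `dir`, invisibly.
#' @export
writeQuantification <- function(quant, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(quant$fits, file.path(dir, "well_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(quant$amplicons, file.path(dir, "amplicon_summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}
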