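# ---------------------------------------------------------------------------
# Per-gene/per-day group comparisons and cycle-wise milk-yield analysis
# ---------------------------------------------------------------------------

#' Normality test (Kolmogorov-Smirnov, Lilliefors-corrected)
#'
#' Tests against a normal with the sample's mean and sd; because those
#' parameters are estimated, the Lilliefors correction is applied by default.
#'
#' @param x Numeric vector, n >= 4.
#' @param lilliefors Use the Lilliefors-corrected p (default); otherwise the
#'   plain one-sample KS p against `pnorm(mean(x), sd(x))`.
#' @return List with `p`, `statistic`, `flag` (`"ok"` or `"zero_variance"`).
#' @export
ksNormality <- function(x, lilliefors = TRUE) {
  x <- x[is.finite(x)]
  .assert(length(x) >= 4, "need n >= 4 for the normality test")
  if (stats::sd(x) == 0)
    return(list(p = 0, statistic = NA_real_, flag = "zero_variance"))
  if (lilliefors && length(x) >= 5) {  # Lilliefors tables start at n = 5
    t <- nortest::lillie.test(x)
  } else {
    t <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(p = t$p.value, statistic = unname(t$statistic), flag = "ok")
}

#' Levene's test for equality of variances
#'
#' Classical Levene (deviations from the group mean, not the median).
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (>= 2 groups, each n >= 2).
#' @return List with `p`, `statistic`, `df`.
#' @export
leveneP <- function(values, groups) {
  groups <- factor(groups)
  .assert(nlevels(groups) >= 2, "need >= 2 groups")
  n <- table(groups)
  .assert(all(n >= 2), "each group needs n >= 2")
  .assert(all(tapply(values, groups, function(v) stats::sd(v) >= 0)),
          "degenerate group")
  lt <- suppressWarnings(car::leveneTest(values, groups, center = mean))
  list(p = lt[["Pr(>F)"]][1], statistic = lt[["F value"]][1],
       df = c(lt$Df[1], lt$Df[2]))
}

#' Two-group comparison with the parametric/non-parametric gate
#'
#' If both groups pass the normality test at `alpha` (groups too small to
#' test, n < 4, are treated as passing -- the reference design's control
#' group has n = 3), a t-test is used: pooled-variance when Levene's p >=
#' `alpha`, Welch otherwise. Otherwise a two-sided Mann-Whitney U test:
#' exact when `min(n) <= 8` and there are no ties, normal approximation with
#' tie correction otherwise. Stars code the final p.
#'
#' @param a,b Numeric vectors (each n >= 3).
#' @param forceTest `NULL` (gate as above), `"t"` or `"mann_whitney"`.
#' @param alpha Gate level (default 0.05).
#' @return One-row data frame: `test` (`t`, `welch_t`, `mann_whitney_u`),
#'   `statistic`, `p`, `stars`, `normality_p_a`, `normality_p_b`,
#'   `levene_p`.
#' @export
compareTwoGroups <- function(a, b, forceTest = NULL, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  .assert(length(a) >= 3 && length(b) >= 3, "need n >= 3 per group")
  normP <- function(x) if (length(x) >= 4 && stats::sd(x) > 0)
    ksNormality(x)$p else NA_real_
  pa <- normP(a); pb <- normP(b)
  bothNormal <- (is.na(pa) || pa >= alpha) && (is.na(pb) || pb >= alpha)
  lev <- tryCatch(leveneP(c(a, b), rep(c("a", "b"), c(length(a), length(b)))),
                  error = function(e) list(p = NA_real_))
  useT <- if (is.null(forceTest)) bothNormal else forceTest == "t"
  if (useT) {
    pooled <- !is.na(lev$p) && lev$p >= alpha
    tt <- stats::t.test(a, b, var.equal = pooled)
    res <- data.frame(test = if (pooled) "t" else "welch_t",
                      statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    exact <- min(length(a), length(b)) <= 8 &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    res <- data.frame(test = "mann_whitney_u",
                      statistic = unname(wt$statistic), p = wt$p.value)
  }
  res$stars <- starCode(res$p)
  res$normality_p_a <- pa; res$normality_p_b <- pb; res$levene_p <- lev$p
  res
}

#' One-way ANOVA for three or more groups
#'
#' @param values Numeric vector.
#' @param groups Grouping vector with >= 3 levels, each n >= 2.
#' @return One-row data frame: `test`, `statistic` (F), `df1`, `df2`, `p`,
#'   `stars`.
#' @export
oneWayAnova <- function(values, groups) {
  groups <- factor(groups)
  .assert(nlevels(groups) >= 3, "need >= 3 groups (use compareTwoGroups)")
  .assert(all(table(groups) >= 2), "each group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  p <- s[["Pr(>F)"]][1]
  if (is.na(p) && s[["Mean Sq"]][1] == 0) p <- 1  # identical groups: F = 0
  data.frame(test = "anova",
             statistic = if (is.na(s[["F value"]][1]) &&
                             s[["Mean Sq"]][1] == 0) 0
             else s[["F value"]][1],
             df1 = s$Df[1], df2 = s$Df[2], p = p, stars = starCode(p))
}

#' Per-gene per-day group comparisons
#'
#' Applies [compareTwoGroups()] (control vs treated) for each gene and
#' sampling day with at least 3 detected values per group.
#'
#' @param panel An [ExpressionPanel-class].
#' @param genes Genes to test (default: all rows).
#' @return Data frame (`gene`, `day`, `n_control`, `n_rbst`, test columns).
#' @export
perDayComparisons <- function(panel, genes = rownames(panel)) {
  stopifnot(is(panel, "ExpressionPanel"))
  cd <- colData(panel)
  out <- list()
  for (g in genes) for (d in sort(unique(cd$day))) {
    sel <- cd$day == d
    x <- assay(panel)[g, sel]
    grp <- cd$group[sel]
    a <- x[grp == "control" & !is.na(x)]
    b <- x[grp == "rbst" & !is.na(x)]
    if (length(a) < 3 || length(b) < 3) next
    r <- compareTwoGroups(a, b)
    out[[length(out) + 1L]] <-
      cbind(data.frame(gene = g, day = d, n_control = length(a),
                       n_rbst = length(b)), r)
  }
  do.call(rbind, out)
}

#' Cycle-wise milk-yield table
#'
#' Mirrors the reference experiment's yield summary: per treatment cycle, the
#' group mean and sd over animal-days, the production difference
#' (`100 * (mean_rbst - mean_control) / mean_control` computed per day, then
#' mean and sd over the cycle's days), and a two-group comparison of the
#' animal-day values.
#'
#' @param yields Data frame with `animal`, `group`, `day`, `kg`.
#' @param design A [StudyDesign-class].
#' @param edges Optional explicit cycle edges, see [assignCycle()].
#' @return Data frame, one row per cycle: `cycle`, `days`, `mean_rbst`,
#'   `sd_rbst`, `mean_control`, `sd_control`, `pct_diff_mean`, `pct_diff_sd`,
#'   `test`, `p`, `stars`.
#' @export
cycleYieldTable <- function(yields, design, edges = NULL) {
  .assert(all(c("animal", "group", "day", "kg") %in% names(yields)),
          "yields needs animal, group, day, kg")
  yields$cycle <- assignCycle(yields$day, design, edges = edges)
  out <- lapply(split(yields, yields$cycle), function(d) {
    rb <- d$kg[d$group == "rbst"]; ct <- d$kg[d$group == "control"]
    if (length(rb) == 0 || length(ct) == 0) {
      warning("cycle ", d$cycle[1], " has no data for one group; omitted")
      return(NULL)
    }
    daily <- vapply(split(d, d$day), function(dd) {
      mc <- mean(dd$kg[dd$group == "control"])
      mr <- mean(dd$kg[dd$group == "rbst"])
      100 * (mr - mc) / mc
    }, numeric(1))
    cmp <- tryCatch(compareTwoGroups(ct, rb),
                    error = function(e) data.frame(
                      test = NA_character_, statistic = NA_real_,
                      p = NA_real_, stars = NA_character_,
                      normality_p_a = NA_real_, normality_p_b = NA_real_,
                      levene_p = NA_real_))
    data.frame(cycle = d$cycle[1],
               days = paste(min(d$day), "to", max(d$day)),
               mean_rbst = mean(rb), sd_rbst = stats::sd(rb),
               mean_control = mean(ct), sd_control = stats::sd(ct),
               pct_diff_mean = mean(daily), pct_diff_sd = stats::sd(daily),
               test = cmp$test, p = cmp$p, stars = cmp$stars,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cycle), ]
}
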