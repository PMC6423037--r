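test_that("Pareto preprocessing matches hand computation and round-trips", {
  x <- cbind(g1 = c(1, 10, 100), g2 = c(2, 4, 8))
  pp <- preprocessPareto(x)
  expect_equal(unname(pp$X[, "g1"]), c(-1, 0, 1))        # log10 sd = 1
  inv <- inversePareto(pp)
  expect_equal(unname(inv), unname(x), tolerance = 1e-10)
  # zero-variance column dropped with warning
  expect_warning(pp2 <- preprocessPareto(cbind(x, flat = c(3, 3, 3))),
                 "zero-variance")
  expect_false("flat" %in% colnames(pp2$X))
  expect_error(preprocessPareto(cbind(g1 = c(1, -1, 2))), "non-positive")
  # class coding
  pp3 <- preprocessPareto(x, y = c("control", "rbst", "rbst"))
  expect_equal(pp3$y, c(0, 1, 1))
})

test_that("NIPALS PCA agrees with the SVD oracle", {
  set.seed(1)
  X <- scale(matrix(rnorm(50), 10, 5), scale = FALSE)
  p <- fitPcaNipals(X, 3)
  sv <- svd(X)
  for (a in 1:3) {
    expect_lt(min(max(abs(p@loadings[, a] - sv$v[, a])),
                  max(abs(p@loadings[, a] + sv$v[, a]))), 1e-6)
    expect_equal(sum(p@scores[, a]^2), sv$d[a]^2, tolerance = 1e-6)
  }
  # orthonormal loadings, orthogonal scores
  expect_equal(crossprod(p@loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  offdiag <- crossprod(p@scores)[lower.tri(diag(3))]
  expect_true(all(abs(offdiag) < 1e-6))
  # R2X per component is non-increasing and sums to <= 1
  expect_true(all(diff(p@r2x) <= 1e-12))
  expect_lte(sum(p@r2x), 1 + 1e-12)
  # rank-1 matrix: one component explains everything
  r1 <- tcrossprod(rnorm(8), rnorm(4))
  p1 <- fitPcaNipals(r1, 1)
  expect_equal(p1@r2x, 1, tolerance = 1e-10)
})

test_that("Hotelling T2 limit reduces to its closed form", {
  set.seed(2)
  X <- scale(matrix(rnorm(40 * 4), 40, 4), scale = FALSE)
  m1 <- fitPcaNipals(X, 1)
  h <- hotellingT2(m1)
  N <- 40
  expect_equal(h$limit, (N^2 - 1) / (N * (N - 1)) * qf(0.95, 1, N - 1),
               tolerance = 1e-12)
  # sample at the scores origin has T2 = 0
  m2 <- fitPcaNipals(rbind(X, 0), 2)
  expect_lt(hotellingT2(m2)$t2[41], 1e-10)
  # alternative variant
  h2 <- hotellingT2(m1, variant = "n1")
  expect_equal(h2$limit, (N - 1) / (N - 1) * qf(0.95, 1, N - 1) * 1,
               tolerance = 1e-12)
})

test_that("Hotelling T2 exceedance is near nominal for normal scores", {
  set.seed(3)
  X <- matrix(rnorm(2000 * 6), 2000, 6)
  X <- scale(X, scale = FALSE)
  m <- fitPcaNipals(X, 2)
  h <- hotellingT2(m)
  rate <- mean(h$t2 > h$limit)
  expect_gt(rate, 0.035); expect_lt(rate, 0.065)
})

test_that("DModX is zero in-plane, near 1 on average, and catches outliers", {
  set.seed(4)
  scoresT <- matrix(rnorm(30 * 2), 30, 2)
  P <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  X <- tcrossprod(scoresT, P)                 # exactly rank 2
  m <- fitPcaNipals(X, 2)
  d <- dmodx(X, m)
  # absolute residual distance (undo the pooled-sd normalisation) is zero
  expect_lt(max(d$dmodx * d$s0), 1e-6)
  # noisy data: normalised DModX has mean about 1
  Xn <- X + matrix(rnorm(length(X), 0, 0.3), nrow(X))
  mn <- fitPcaNipals(Xn, 2)
  dn <- dmodx(Xn, mn)
  expect_gt(mean(dn$dmodx), 0.8); expect_lt(mean(dn$dmodx), 1.1)
  # a sample with a 10x residual exceeds the critical limit
  Xo <- rbind(Xn, Xn[1, ] + rnorm(6, 0, 3))
  mo <- fitPcaNipals(Xo, 2)
  do <- dmodx(Xo, mo)
  expect_gt(do$dmodx[31], do$limit)
})

test_that("outlier flagging is a single-pass union of the two criteria", {
  set.seed(5)
  X <- scale(matrix(rnorm(200 * 6), 200, 6), scale = FALSE)
  rownames(X) <- paste0("s", 1:200)
  m <- fitPcaNipals(X, 2)
  fo <- flagOutliers(X, m)
  rate <- length(fo$excluded) / 200
  expect_gt(rate, 0.02); expect_lt(rate, 0.15)
  # injected extreme sample is flagged
  X2 <- rbind(X, out = rep(10, 6))
  m2 <- fitPcaNipals(X2, 2)
  expect_true("out" %in% flagOutliers(X2, m2)$excluded)
  # a tiny clean set may legitimately flag nothing
  X3 <- scale(matrix(rnorm(10 * 4, sd = 0.1), 10, 4), scale = FALSE)
  m3 <- fitPcaNipals(X3, 1)
  expect_true(length(flagOutliers(X3, m3)$excluded) >= 0)
})

test_that("OPLS-DA separates predictive from orthogonal variation", {
  set.seed(6)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  yc <- y - mean(y)
  nuisance <- rnorm(n, 0, 3)                  # strong y-unrelated direction
  X <- cbind(yc * 2 + rnorm(n, 0, .5) + nuisance,
             yc * 1.5 + rnorm(n, 0, .5) - nuisance,
             nuisance + rnorm(n, 0, .5),
             rnorm(n, 0, .5))
  X <- scale(X, scale = FALSE)
  m <- fitOplsda(X, y, nOrth = 1)
  # predictive score correlates with y more strongly than the plain first
  # PLS component on undeflated X
  w0 <- crossprod(X, yc); w0 <- w0 / sqrt(sum(w0^2))
  t0 <- drop(X %*% w0)
  expect_gt(abs(cor(m@scores, y)), abs(cor(t0, y)))
  # orthogonal score tracks the nuisance direction
  expect_gt(abs(cor(m@orthoScores[, 1], nuisance)), 0.8)
  # predictive score orthogonal to every orthogonal score
  expect_lt(abs(sum(m@scores * m@orthoScores[, 1])), 1e-6)
  expect_gte(m@r2y, 0); expect_lte(m@r2y, 1)
  expect_lte(as.numeric(m@q2), m@r2y + 1e-9)
})

test_that("uninformative X and degenerate inputs are handled", {
  set.seed(7)
  y <- rep(c(0, 1), each = 10)
  X <- matrix(rep(rnorm(20), 3), 20, 3)       # identical columns
  X[, 2] <- X[, 2] + rnorm(20, 0, 1e-14)
  Xz <- scale(matrix(rnorm(60), 20, 3), scale = FALSE)
  # y-covariance numerically zero: flag uninformative
  m <- fitOplsda(Xz * 0, y, nOrth = 0)
  expect_true(m@uninformative)
  expect_error(fitOplsda(Xz, rep(1, 20)), "two classes")
  expect_error(crossValidateQ2(Xz, y, folds = 1), ">= 2")
  expect_error(crossValidateQ2(Xz, y, folds = 25), "folds")
})

test_that("cross-validated Q2 rewards separable classes and punishes noise", {
  set.seed(8)
  y <- rep(c(0, 1), 30)
  X <- cbind(sep = y * 10 + rnorm(60, 0, 0.3),
             matrix(rnorm(60 * 3), 60))
  X <- scale(X, scale = FALSE)
  expect_gt(crossValidateQ2(X, y, nOrth = 0), 0.9)
  q2perm <- replicate(30, {
    crossValidateQ2(X, sample(y), nOrth = 0)
  })
  expect_gte(mean(q2perm <= 0.05), 0.9)
})

test_that("permuting y destroys Q2, CV-ANOVA and S-plot structure", {
  fit <- fitSimStudy(71)
  set.seed(9)
  yPerm <- sample(fit$y)
  q2p <- crossValidateQ2(fit$X, yPerm, nOrth = fit$model@nOrth)
  expect_lt(as.numeric(q2p), 0.1)
  cap <- cvAnova(fit$X, yPerm, nOrth = fit$model@nOrth)
  expect_gt(cap$p, 0.01)
  mp <- fitOplsda(fit$X, yPerm, nOrth = 0L)
  spp <- sPlot(mp, fit$X)
  expect_lt(max(abs(spp$pcorr1)), max(abs(fit$splot$pcorr1)))
})

test_that("CV-ANOVA responds to separation and truncates under the null", {
  set.seed(10)
  y <- rep(c(0, 1), each = 15)
  Xsep <- scale(cbind(y * 8 + rnorm(30, 0, 0.1),
                      matrix(rnorm(90), 30)), scale = FALSE)
  expect_lt(cvAnova(Xsep, y, nOrth = 0)$p, 1e-6)
  # null: F truncated at zero gives p = 1 (not an error)
  Xnull <- scale(matrix(rnorm(30 * 4), 30, 4), scale = FALSE)
  ca <- cvAnova(Xnull, y, nOrth = 0)
  expect_gte(ca$F, 0)
  expect_lte(ca$p, 1)
})

test_that("S-plot coordinates are covariance and correlation with the score", {
  set.seed(11)
  t <- rnorm(100)
  X <- cbind(exact = t, inv = -t, noise = rnorm(100))
  X <- scale(X, scale = FALSE)
  y <- as.numeric(t > 0)
  m <- fitOplsda(X, y, nOrth = 0)
  sp <- sPlot(m, X)
  expect_equal(abs(sp$pcorr1[sp$gene == "exact"]), 1, tolerance = 2e-3)
  expect_equal(abs(sp$pcorr1[sp$gene == "inv"]), 1, tolerance = 2e-3)
  expect_equal(sign(sp$p1), sign(sp$pcorr1))
  expect_equal(sp$p1, drop(crossprod(X, m@scores)) / 99, tolerance = 1e-10,
               ignore_attr = TRUE)
  # a gene independent of the fitted score stays near zero correlation
  set.seed(12)
  small <- replicate(40, {
    t <- rnorm(200)
    X <- scale(cbind(a = t, b = t + rnorm(200, 0, 0.3)), scale = FALSE)
    m <- fitOplsda(X, as.numeric(t > 0), nOrth = 0)
    g <- scale(cbind(X, g = rnorm(200)), scale = FALSE)
    abs(sPlot(m, g)$pcorr1[3]) < 0.2
  })
  expect_gte(mean(small), 0.95)
})

test_that("biomarker ranking orders by |pcorr1| with a panel threshold", {
  sp <- data.frame(gene = c("a", "b", "c"), p1 = c(0.5, -0.4, 0.05),
                   pcorr1 = c(0.9, -0.6, 0.1), flag = "ok")
  r <- rankBiomarkers(sp, threshold = 0.4)
  expect_equal(r$gene, c("a", "b", "c"))
  expect_equal(r$in_panel, c(TRUE, TRUE, FALSE))
  expect_equal(rankBiomarkers(sp, threshold = 0)$in_panel, rep(TRUE, 3))
  spz <- data.frame(gene = "a", p1 = 0, pcorr1 = 0, flag = "ok")
  expect_false(any(rankBiomarkers(spz)$in_panel))
})

test_that("a simulated study yields the injected four-marker panel", {
  fit <- fitSimStudy(81)
  top4 <- fit$splot$gene[order(-abs(fit$splot$pcorr1))][1:4]
  expect_setequal(top4, c("CCND1", "IGF1R", "TNF", "IL1B"))
  # treated-positive orientation: the markers sit in the upper right corner
  mk <- fit$splot[fit$splot$gene %in% top4, ]
  expect_true(all(mk$p1 > 0 & mk$pcorr1 > 0))
})
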