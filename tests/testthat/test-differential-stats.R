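test_that("rank-sum p for fully separated groups matches exact enumeration", {
  m <- rbind(sep = c(1:5, 6:10))
  res <- differentialDistribution(m, rep(c("A", "B"), each = 5))
  expect_equal(res$p, 2 / 252, tolerance = 1e-12)         # 2 / C(10,5)
  expect_equal(res$p, enumerateRankSumP(1:5, 6:10), tolerance = 1e-12)
  expect_true(res$significant)                             # |d| >> 1, p < .05
})

test_that("exact Wilcoxon p agrees with brute-force enumeration at small n", {
  set.seed(31)
  for (i in 1:8) {
    a <- sample(100, 4); b <- sample(200, 5)
    while (length(intersect(a, b))) b <- sample(200, 5)
    res <- differentialDistribution(rbind(f = c(a, b)),
                                    rep(c("A", "B"), c(4, 5)))
    expect_equal(res$p, enumerateRankSumP(a, b), tolerance = 1e-12)
  }
})

test_that("identical groups are never significant and ES is zero", {
  m <- rbind(f = rep(c(3, 1, 4, 1, 5), 2))
  res <- differentialDistribution(m, rep(c("A", "B"), each = 5))
  expect_equal(res$es, 0)
  expect_false(res$significant)
  flat <- differentialDistribution(rbind(f = rep(1, 10)),
                                   rep(c("A", "B"), each = 5))
  expect_equal(flat$p, 1)
  expect_true(flat$constant)
})

test_that("effect size implements Cohen's d and its paired analogue", {
  a <- c(1, 2, 3, 4); b <- c(5, 6, 7, 8)
  res <- differentialDistribution(rbind(f = c(a, b)),
                                  rep(c("A", "B"), each = 4))
  pooled <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(res$es, (mean(a) - mean(b)) / pooled)
  b2 <- c(5, 7, 6, 9)                         # non-degenerate paired diffs
  dres <- differentialDistribution(rbind(f = c(a, b2)),
                                   rep(c("A", "B"), each = 4), paired = TRUE)
  d <- a - b2
  expect_equal(dres$es, mean(d) / sd(d))
  expect_identical(dres$test, "signed-rank")
})

test_that("BH q-values follow the step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  m <- matrix(rnorm(4 * 10), nrow = 4)
  res <- differentialDistribution(m, rep(c("A", "B"), each = 5))
  expect_equal(res$q, stepUpBH(res$p), tolerance = 1e-12)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))           # worked example
  set.seed(17)
  for (i in 1:10) {
    pv <- runif(50)
    expect_equal(p.adjust(pv, "BH"), stepUpBH(pv), tolerance = 1e-12)
  }
  expect_true(all(res$q >= res$p))
})

test_that("the combined significance rule is q < 0.1 or (p < 0.05 and |ES| > 1)", {
  # large ES, small p, but q pushed above 0.1 by many null features
  set.seed(5)
  m <- rbind(matrix(rnorm(60 * 20), nrow = 60),
             sig = c(rnorm(10), rnorm(10, mean = 1.6)))
  res <- differentialDistribution(m, rep(c("A", "B"), each = 10))
  i <- which(res$feature == "sig")
  if (res$q[i] >= 0.1 && res$p[i] < 0.05 && abs(res$es[i]) > 1)
    expect_true(res$significant[i])
  expect_identical(res$significant,
                   res$q < 0.1 | (res$p < 0.05 & abs(res$es) > 1))
})

test_that("Fisher tests match hypergeometric enumeration", {
  same <- differentialCounts(matrix(c(5, 5, 95, 95), 2))
  expect_equal(same$p, 1)
  tb <- matrix(c(20, 0, 80, 100), 2)
  res <- differentialCounts(tb)
  expect_equal(res$p, enumerateFisherP(tb), tolerance = 1e-12)
  # all 2x2 tables with total <= 30 (margins from a coarse sweep)
  for (a in 0:6) for (b in 0:4) for (cc in 0:4) for (d in 0:5) {
    tab <- matrix(c(a, cc, b, d), 2)
    if (sum(tab) == 0) next
    expect_equal(differentialCounts(tab)$p, enumerateFisherP(tab),
                 tolerance = 1e-12)
  }
  expect_error(differentialCounts(matrix(0, 2, 2)), "empty")
  expect_error(differentialCounts(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Z-scoring is idempotent and stratifies opposite-sign groups", {
  m <- matrix(rnorm(5 * 12), nrow = 5,
              dimnames = list(paste0("f", 1:5), paste0("S", 1:12)))
  labels <- rep(c("R", "NR"), each = 6)
  zm <- zscoreStratify(m, rownames(m), labels)
  expect_true(all(abs(colMeans(zm@z)) < 1e-8))
  expect_true(all(abs(apply(zm@z, 2, sd) - 1) < 1e-8))
  z2 <- zscoreStratify(t(zm@z), rownames(m), labels)   # Z of Z is a no-op
  expect_equal(z2@z, zm@z, tolerance = 1e-12)

  flat <- zscoreStratify(rbind(f1 = rep(2, 12), f2 = rnorm(12)),
                         c("f1", "f2"), labels)
  expect_true(all(flat@z[, "f1"] == 0))

  # +1 / -1 profiles: the dendrogram cut at 2 separates the groups perfectly
  sep <- matrix(rep(c(1, -1), each = 6), nrow = 3, ncol = 12, byrow = TRUE,
                dimnames = list(paste0("f", 1:3), paste0("S", 1:12)))
  sep <- sep + matrix(rnorm(36, sd = 0.01), 3)
  zsep <- zscoreStratify(sep, rownames(sep), labels)
  cl <- cutree(hclust(dist(zsep@z), "ward.D2"), k = 2)
  expect_equal(adjustedRand(cl, labels), 1)
  expect_error(zscoreStratify(m, character(0), labels), "empty")
})

test_that("substantial Z shifts are flagged above the 0.5 rule", {
  expect_true(substantialZShift(c(f = -0.3), c(f = 0.3)))   # difference 0.6
  expect_false(substantialZShift(c(f = 0), c(f = 0.5)))     # not strictly >
  expect_true(substantialZShift(c(f = 0.2), c(f = -0.4)))
})

test_that("Mahalanobis attribution implements the per-feature rule", {
  subjects <- c("out", paste0("A", 1:5), paste0("B", 1:5))
  gA <- paste0("A", 1:5); gB <- paste0("B", 1:5)
  a <- c(10, 12, 14, 16, 18)                  # mean 14, sd ~3.16
  m <- rbind(atMeanA = c(14, a, a + 100),
             oneSdA = c(14 + sd(a), a, a + 100))
  colnames(m) <- subjects
  res <- mahalanobisAttribution(m, "out", gA, gB)
  expect_equal(res$dA[1], 0)
  expect_equal(res$dA[2], 1)

  # delta rule: dA = 1.4, dB = 0.9 -> 0.5 > 0.3 -> attributed
  mkGroup <- function(mean, sd, n = 5) mean + sd * scale(seq_len(n))[, 1]
  gAvals <- mkGroup(0, 1); gBvals <- mkGroup(2.3, 1)
  x <- 1.4                                     # |x-0|/1 = 1.4, |x-2.3|/1 = 0.9
  m2 <- rbind(f = c(x, gAvals, gBvals)); colnames(m2) <- subjects
  res2 <- mahalanobisAttribution(m2, "out", gA, gB, threshold = 0.3)
  expect_equal(res2$delta, 0.5)
  expect_true(res2$attributed)

  # symmetry: swapping the groups negates delta
  res3 <- mahalanobisAttribution(m2, "out", gB, gA, threshold = 0.3)
  expect_equal(res3$delta, -res2$delta)

  flatRow <- rbind(f = c(1, rep(2, 5), rnorm(5))); colnames(flatRow) <- subjects
  resFlat <- mahalanobisAttribution(flatRow, "out", gA, gB)
  expect_true(resFlat$skipped)
  expect_false(resFlat$attributed)
})
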