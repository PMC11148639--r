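test_that("Spearman matrix matches the rank-then-Pearson oracle, with ties", {
  x <- c(1, 2, 3, 4)
  m <- rbind(x = x, up = x^3, down = -x, tied = c(1, 1, 2, 2))
  rho <- spearmanMatrix(m)
  expect_equal(rho["x", "up"], 1)
  expect_equal(rho["x", "down"], -1)
  expect_equal(rho["x", "tied"], cor(rank(x), rank(c(1, 1, 2, 2))))
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 4))
  expect_error(spearmanMatrix(m[, 1:2]), "3 subjects")
})

test_that("constant features get zero correlation and are flagged", {
  m <- rbind(f1 = c(1, 2, 3, 4), flat = c(5, 5, 5, 5))
  rho <- spearmanMatrix(m)
  expect_equal(rho["f1", "flat"], 0)
  expect_equal(rho["flat", "flat"], 1)
  expect_identical(attr(rho, "constant"), "flat")
})

test_that("distance transform is 1 - rho^4 and sign-blind", {
  rhos <- c(-1, -0.5, 0, 0.5, 1)
  d <- correlationToDistance(matrix(rhos, 1, 5))
  expect_equal(as.vector(d[1, ]), c(0, 0.9375, 1, 0.9375, 0))
  expect_error(correlationToDistance(matrix(1.5)), "\\[-1, 1\\]")
  # property: d(rho) == d(-rho) over a grid
  g <- seq(-1, 1, by = 0.05)
  expect_equal(1 - g^4, 1 - (-g)^4)
  dg <- correlationToDistance(rbind(g))
  expect_equal(as.vector(dg), as.vector(correlationToDistance(rbind(-g))))
})

test_that("two perfectly separated blocks are cut at k = 2", {
  d <- blockDistance(c(5, 5))
  a <- clusterModules(d, kRange = 2:5)
  expect_identical(selectedK(a), 2L)
  expect_equal(adjustedRand(moduleOf(a), rep(1:2, each = 5)), 1)
  # silhouette agrees with the brute-force oracle at every k
  for (k in 2:5) {
    cl <- cutree(a@linkage, k = k)
    expect_equal(unname(silhouetteTrace(a)[as.character(k)]),
                 bruteSilhouette(d, cl), tolerance = 1e-12)
  }
})

test_that("equal pairwise distances give silhouette 0 and the smallest k", {
  d <- matrix(1, 6, 6); diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("f", 1:6)
  a <- clusterModules(d, kRange = 2:5)
  expect_true(all(abs(silhouetteTrace(a)) < 1e-12))
  expect_identical(selectedK(a), 2L)           # tie -> smallest k
  expect_error(clusterModules(matrix(0, 4, 4)), "degenerate")
})

test_that("planted modules are recovered on a synthetic cohort", {
  co <- generateFeatureCohort(CohortSpec(20, 8, 6, withinModuleRho = 0.8,
                                         seed = 2))
  tab <- imputeColumnMean(co$table)
  a <- clusterModules(correlationToDistance(spearmanMatrix(tab)))
  expect_identical(selectedK(a), 8L)
  expect_gte(adjustedRand(moduleOf(a), moduleOf(co$truth)), 0.9)
})

test_that("silhouette selection is invariant to feature ordering", {
  co <- generateFeatureCohort(CohortSpec(15, 4, 5, withinModuleRho = 0.7,
                                         seed = 9))
  m <- featureValues(imputeColumnMean(co$table))
  a1 <- clusterModules(correlationToDistance(spearmanMatrix(m)))
  perm <- withr::with_seed(1, sample(nrow(m)))
  a2 <- clusterModules(correlationToDistance(spearmanMatrix(m[perm, ])))
  expect_identical(selectedK(a1), selectedK(a2))
  expect_equal(silhouetteTrace(a1), silhouetteTrace(a2), tolerance = 1e-12)
  expect_equal(adjustedRand(moduleOf(a1), moduleOf(a2)[rownames(m)]), 1)
})

test_that("PC1 summaries behave on degenerate and equicorrelated modules", {
  co <- generateFeatureCohort(CohortSpec(20, 1, 6, withinModuleRho = 0.8,
                                         seed = 4))
  m <- featureValues(co$table)
  # singleton module: PC1 equals the Z-scored feature, variance explained 1
  single <- new("ModuleAssignment",
                moduleOfFeature = setNames(rep(1L, 1), rownames(m)[1]),
                kSelected = 2L, silhouetteByK = c("2" = 0.5, "3" = 0.1),
                linkage = NULL, constantFeatures = character(0))
  sc <- summarizeModules(m[1, , drop = FALSE], single)
  z <- (m[1, ] - mean(m[1, ])) / sd(m[1, ])
  expect_equal(unname(scoreMatrix(sc)[, 1]), unname(z))
  expect_equal(varianceExplained(sc), 1)

  # two perfectly correlated features: variance explained 1, PC1 ~ common Z
  dup <- rbind(a = m[1, ], b = 2 * m[1, ] + 3)
  dupAsg <- new("ModuleAssignment",
                moduleOfFeature = setNames(c(1L, 1L), c("a", "b")),
                kSelected = 2L, silhouetteByK = c("2" = 0.5, "3" = 0.1),
                linkage = NULL, constantFeatures = character(0))
  sc2 <- summarizeModules(dup, dupAsg)
  expect_equal(varianceExplained(sc2), 1)
  expect_equal(abs(cor(scoreMatrix(sc2)[, 1], m[1, ])), 1)
  expect_gte(cor(scoreMatrix(sc2)[, 1], z), 0)  # orientation rule

  # 6-feature equicorrelated module: leading eigenvalue (1 + 5 rho) / 6
  full <- summarizeModules(m, new("ModuleAssignment",
    moduleOfFeature = setNames(rep(1L, nrow(m)), rownames(m)),
    kSelected = 2L, silhouetteByK = c("2" = 0.5, "3" = 0.1),
    linkage = NULL, constantFeatures = character(0)))
  expect_lt(abs(varianceExplained(full) - (1 + 5 * 0.8) / 6), 0.1)
})

test_that("module scores are centred, oriented and bounded below by member correlation", {
  co <- generateFeatureCohort(CohortSpec(20, 5, 6, withinModuleRho = 0.6,
                                         seed = 5))
  tab <- imputeColumnMean(co$table)
  res <- discoverModules(tab)
  sc <- res$scores
  expect_true(all(abs(colMeans(scoreMatrix(sc))) < 1e-8))
  rho <- spearmanMatrix(tab)
  part <- moduleOf(res$assignment)
  for (i in seq_along(varianceExplained(sc))) {
    members <- names(part)[part == i]
    if (length(members) < 2) next
    sub <- abs(rho[members, members])
    meanAbs <- mean(sub[upper.tri(sub)])
    expect_gte(varianceExplained(sc)[i], meanAbs - 0.05)
    # orientation: PC1 correlates non-negatively with the mean member Z
    z <- t(scale(t(featureValues(tab)[members, ])))
    expect_gte(cor(scoreMatrix(sc)[, i], colMeans(z)), 0)
  }
})

test_that("a module of only constant features is an error", {
  m <- rbind(flat1 = rep(1, 10), flat2 = rep(2, 10))
  asg <- new("ModuleAssignment",
             moduleOfFeature = setNames(c(1L, 1L), c("flat1", "flat2")),
             kSelected = 2L, silhouetteByK = c("2" = 0.5, "3" = 0.1),
             linkage = NULL, constantFeatures = c("flat1", "flat2"))
  expect_error(summarizeModules(m, asg), "non-constant")
})
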