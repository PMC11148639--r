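# Immune module discovery: Spearman correlation across subjects, the signed
# distance transform d = 1 - rho^4, Ward clustering on the precomputed
# dissimilarity with silhouette-based selection of the module count, and PC1
# summarization of Z-scored member features.

#' Pairwise Spearman correlation of immune features
#'
#' Rank correlation (average ranks for ties) between all pairs of features
#' across subjects. Zero-variance features are undefined under ranking; their
#' correlation with every other feature is set to 0 and the features are
#' reported in the \code{constant} attribute.
#'
#' @param x an [ImmuneFeatureTable-class] (fully imputed) or a features x
#'   subjects numeric matrix.
#' @return A features x features correlation matrix with unit diagonal and an
#'   attribute \code{constant} naming zero-variance features.
#' @export
spearmanMatrix <- function(x) {
  m <- if (is(x, "ImmuneFeatureTable")) featureValues(x) else as.matrix(x)
  if (ncol(m) < 3L) stop("at least 3 subjects required")
  if (anyNA(m)) stop("table must be fully imputed before correlation")
  constant <- apply(m, 1L, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  if (any(constant)) {
    rho[constant, ] <- 0
    rho[, constant] <- 0
  }
  diag(rho) <- 1
  attr(rho, "constant") <- rownames(m)[constant]
  rho
}

#' Transform correlations into module-discovery distances
#'
#' Elementwise \eqn{d = 1 - \rho^4}. Raising the correlation to the fourth
#' power removes the sign — strongly anticorrelated feature pairs are as
#' close as strongly correlated ones — and inflates the distance between
#' features with only moderate correlation.
#'
#' @param corr correlation matrix with entries in [-1, 1].
#' @return Distance matrix with zero diagonal and entries in [0, 1];
#'   symmetric in the sign of \code{corr}.
#' @examples
#' correlationToDistance(matrix(c(1, -0.5, -0.5, 1), 2))
#' @export
correlationToDistance <- function(corr) {
  corr <- as.matrix(corr)
  if (any(abs(corr) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  corr <- pmin(pmax(corr, -1), 1)
  d <- 1 - corr^4
  diag(d) <- 0
  dimnames(d) <- dimnames(corr)
  d
}

#' Cluster features into immune modules
#'
#' Ward agglomeration on the precomputed dissimilarity (the Lance-Williams
#' Ward update applied directly to the given distances, i.e. "Ward on
#' dissimilarities"), with the tree cut at every candidate module count k.
#' The mean silhouette width — computed against the same distance matrix,
#' with singleton clusters contributing width 0 — is recorded per k, and the
#' silhouette-maximal k is selected, ties broken toward smaller k.
#'
#' @param dist features x features distance matrix (e.g. from
#'   [correlationToDistance()]).
#' @param kRange integer vector of candidate module counts; default
#'   \code{2:min(nFeatures - 1, 100)}.
#' @param method \code{hclust} agglomeration method (default \code{"ward.D"}).
#' @return A [ModuleAssignment-class].
#' @examples
#' cohort <- generateFeatureCohort(CohortSpec(20, 4, 5, seed = 1))
#' tab <- imputeColumnMean(cohort$table)
#' mod <- clusterModules(correlationToDistance(spearmanMatrix(tab)))
#' selectedK(mod)
#' @export
clusterModules <- function(dist, kRange = NULL, method = "ward.D") {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 3L) stop("at least 3 features required")
  if (all(dist == 0)) stop("degenerate distance matrix (all zeros)")
  if (is.null(kRange)) kRange <- 2L:min(n - 1L, 100L)
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stop("kRange must lie within [2, nFeatures - 1]")

  tree <- stats::hclust(stats::as.dist(dist), method = method)
  sil <- vapply(kRange, function(k) {
    cl <- stats::cutree(tree, k = k)
    sw <- cluster::silhouette(cl, dmatrix = dist)
    if (is.matrix(sw)) mean(sw[, "sil_width"]) else 0
  }, numeric(1))
  names(sil) <- kRange
  kSel <- kRange[which.max(sil)]   # which.max takes the first (smallest k) tie
  part <- stats::cutree(tree, k = kSel)
  new("ModuleAssignment",
      moduleOfFeature = part, kSelected = as.integer(kSel),
      silhouetteByK = sil, linkage = tree,
      constantFeatures = attr(dist, "constant") %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize each module by its first principal component
#'
#' Per module, member features are Z-scored over subjects (zero-variance
#' features yield an all-zero Z column), the first principal component of the
#' Z-scored block is computed, and its sign is oriented so the PC1 score
#' correlates non-negatively with the mean member Z-score — making scores
#' deterministic across runs and platforms. The per-module variance explained
#' by PC1 is reported; for an equicorrelated module of m features with
#' correlation rho it approaches \eqn{(1 + (m-1)\rho)/m}.
#'
#' @param x an [ImmuneFeatureTable-class] (fully imputed) or features x
#'   subjects matrix.
#' @param assignment a [ModuleAssignment-class] covering every feature of
#'   \code{x}.
#' @return A [ModuleScores-class]; scores are subjects x modules with zero
#'   column means.
#' @export
summarizeModules <- function(x, assignment) {
  m <- if (is(x, "ImmuneFeatureTable")) featureValues(x) else as.matrix(x)
  if (ncol(m) < 2L) stop("at least 2 subjects required")
  part <- moduleOf(assignment)
  if (!all(rownames(m) %in% names(part)))
    stop("assignment must cover every feature")
  mods <- sort(unique(part))
  z <- t(apply(m, 1L, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(z) <- dimnames(m)

  scores <- matrix(0, nrow = ncol(m), ncol = length(mods),
                   dimnames = list(colnames(m), paste0("module", mods)))
  loadings <- vector("list", length(mods))
  names(loadings) <- colnames(scores)
  ve <- numeric(length(mods))
  orient <- numeric(length(mods))
  for (i in seq_along(mods)) {
    members <- names(part)[part == mods[i]]
    block <- t(z[members, , drop = FALSE])    # subjects x members
    if (all(block == 0))
      stop("module ", mods[i], " has no non-constant features")
    pc <- stats::prcomp(block, center = FALSE, scale. = FALSE)
    load <- stats::setNames(pc$rotation[, 1L], colnames(block))
    score <- as.vector(block %*% load)
    meanZ <- rowMeans(block)
    flip <- sum(score * meanZ)
    sgn <- if (flip < 0) -1 else 1
    scores[, i] <- sgn * score
    loadings[[i]] <- sgn * load
    ve[i] <- pc$sdev[1L]^2 / sum(pc$sdev^2)
    orient[i] <- sgn
  }
  new("ModuleScores", scores = scores, loadings = loadings,
      varianceExplained = ve, orientation = orient)
}

#' Discover and summarize immune modules in one call
#'
#' Convenience wrapper: Spearman matrix, distance transform, Ward/silhouette
#' clustering and PC1 summarization.
#'
#' @inheritParams clusterModules
#' @param x an [ImmuneFeatureTable-class], fully imputed.
#' @return list with \code{assignment} ([ModuleAssignment-class]) and
#'   \code{scores} ([ModuleScores-class]).
#' @export
discoverModules <- function(x, kRange = NULL, method = "ward.D") {
  rho <- spearmanMatrix(x)
  d <- correlationToDistance(rho)
  attr(d, "constant") <- attr(rho, "constant")
  assignment <- clusterModules(d, kRange = kRange, method = method)
  list(assignment = assignment, scores = summarizeModules(x, assignment))
}
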