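# Companion statistics: Wilcoxon differential testing with BH correction and
# the combined significance rule q < 0.1 or (p < 0.05 and |ES| > 1), Fisher
# tests for count data, Z-score stratification, and per-feature Mahalanobis
# outlier attribution.

# Cohen's d with pooled SD (unpaired); 0 when the pooled SD is 0.
.cohensD <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) return(0)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Differential distribution testing of immune features
#'
#' Per feature, compares the two groups with the Wilcoxon rank-sum test
#' (unpaired) or Wilcoxon signed-rank test (paired); p-values are exact for
#' small samples without ties and use the tie-corrected normal approximation
#' otherwise. Benjamini-Hochberg q-values are computed over the tested
#' feature set. The effect size is Cohen's d (difference of means over the
#' pooled standard deviation) for unpaired comparisons and the mean paired
#' difference over the standard deviation of differences for paired ones.
#' A feature is flagged significant when \code{q < qCut} or
#' (\code{p < pCut} and \code{|ES| > esCut}).
#'
#' @param x an [ImmuneFeatureTable-class] or features x subjects matrix.
#' @param groups binary labels per subject (factor or coercible). For paired
#'   tests the two groups are the two conditions, in matched subject order.
#' @param paired logical; use the signed-rank test on matched pairs.
#' @param qCut,pCut,esCut significance-rule thresholds (defaults 0.1, 0.05, 1).
#' @return A [S4Vectors::DataFrame] with one row per feature: \code{test},
#'   \code{p}, \code{q}, \code{es}, group means and medians, \code{constant}
#'   flag and \code{significant}.
#' @examples
#' m <- rbind(f1 = c(1:5, 6:10), f2 = rnorm(10))
#' differentialDistribution(m, rep(c("A", "B"), each = 5))
#' @export
differentialDistribution <- function(x, groups, paired = FALSE,
                                     qCut = 0.1, pCut = 0.05, esCut = 1) {
  m <- if (is(x, "ImmuneFeatureTable")) featureValues(x) else as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]
  if (paired && sum(g1) != sum(g2))
    stop("paired comparison needs equal group sizes (matched pairs)")
  if (!paired && (sum(g1) < 2L || sum(g2) < 2L))
    stop("need at least 2 subjects per group")

  res <- lapply(seq_len(nrow(m)), function(i) {
    a <- m[i, g1]; b <- m[i, g2]
    constant <- stats::sd(c(a, b)) == 0
    if (constant) {
      p <- 1; es <- 0
    } else if (paired) {
      d <- a - b
      p <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
      es <- if (stats::sd(d) == 0) 0 else mean(d) / stats::sd(d)
    } else {
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      es <- .cohensD(a, b)
    }
    c(p = p, es = es, constant = constant,
      mean1 = mean(a), mean2 = mean(b),
      median1 = stats::median(a), median2 = stats::median(b))
  })
  res <- do.call(rbind, res)
  res <- matrix(as.numeric(res), nrow = nrow(res),
                dimnames = list(NULL, colnames(res)))
  q <- stats::p.adjust(res[, "p"], method = "BH")
  DataFrame(
    feature = rownames(m) %||% paste0("feature", seq_len(nrow(m))),
    test = if (paired) "signed-rank" else "rank-sum",
    p = unname(res[, "p"]), q = unname(q), es = unname(res[, "es"]),
    mean1 = unname(res[, "mean1"]), mean2 = unname(res[, "mean2"]),
    median1 = unname(res[, "median1"]), median2 = unname(res[, "median2"]),
    constant = unname(as.logical(res[, "constant"])),
    significant = unname(q < qCut |
                           (res[, "p"] < pCut & abs(res[, "es"]) > esCut)))
}

#' Differential count testing (Fisher's exact test)
#'
#' Two-sided Fisher's exact test per 2x2 contingency table, with
#' Benjamini-Hochberg correction across the tested units.
#'
#' @param tables list of 2x2 matrices (or a single 2x2 matrix), one per unit.
#' @param qCut BH significance cutoff (default 0.1).
#' @return A [S4Vectors::DataFrame] with \code{p}, \code{q}, odds ratio and
#'   \code{significant}.
#' @export
differentialCounts <- function(tables, qCut = 0.1) {
  if (is.matrix(tables)) tables <- list(tables)
  res <- lapply(tables, function(tb) {
    tb <- as.matrix(tb)
    if (!identical(dim(tb), c(2L, 2L))) stop("each unit must be a 2x2 table")
    if (any(tb < 0) || any(tb != round(tb))) stop("cells must be non-negative integers")
    if (all(tb == 0)) stop("empty contingency table")
    ft <- stats::fisher.test(tb)
    c(p = ft$p.value, or = unname(ft$estimate))
  })
  res <- do.call(rbind, res)
  q <- stats::p.adjust(res[, "p"], method = "BH")
  DataFrame(unit = names(tables) %||% paste0("unit", seq_along(tables)),
            p = unname(res[, "p"]), q = unname(q),
            oddsRatio = unname(res[, "or"]), significant = unname(q < qCut))
}

#' Z-score stratification of selected features
#'
#' Column-wise Z-scores the selected features over subjects (constant columns
#' become all-zero), hierarchically clusters subjects (Ward on Euclidean
#' distances between Z rows) and reports the dendrogram leaf order together
#' with per-group mean Z per feature.
#'
#' @param x an [ImmuneFeatureTable-class] or features x subjects matrix.
#' @param features character, features to include (must exist).
#' @param labels group label per subject.
#' @return A [ZMatrix-class].
#' @export
zscoreStratify <- function(x, features, labels) {
  m <- if (is(x, "ImmuneFeatureTable")) featureValues(x) else as.matrix(x)
  if (!length(features)) stop("empty feature list")
  absent <- setdiff(features, rownames(m))
  if (length(absent))
    stop("feature(s) absent: ", paste(absent, collapse = ", "))
  z <- apply(m[features, , drop = FALSE], 1L, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })                                       # subjects x features
  rownames(z) <- colnames(m)
  labels <- stats::setNames(as.character(labels), rownames(z))
  ord <- if (nrow(z) > 2L)
    stats::hclust(stats::dist(z), method = "ward.D2")$order
  else seq_len(nrow(z))
  groups <- unique(labels)
  gm <- t(vapply(groups, function(g)
    colMeans(z[labels == g, , drop = FALSE]), numeric(ncol(z))))
  rownames(gm) <- groups
  new("ZMatrix", z = z, subjectOrder = as.integer(ord),
      groupLabel = labels, groupMeanZ = gm)
}

#' Flag substantial mean Z-score changes between timepoints
#'
#' A feature shows a substantial change when the absolute difference between
#' its mean Z-scores at the two timepoints exceeds the threshold
#' (default 0.5).
#'
#' @param meanZ1,meanZ2 numeric vectors of mean Z-scores per feature at the
#'   two timepoints (matched by name if named).
#' @param threshold flag threshold on |difference| (default 0.5).
#' @return named logical vector.
#' @examples
#' substantialZShift(c(f1 = -0.3), c(f1 = 0.3))  # difference 0.6 -> TRUE
#' @export
substantialZShift <- function(meanZ1, meanZ2, threshold = 0.5) {
  if (!is.null(names(meanZ1)) && !is.null(names(meanZ2)))
    meanZ2 <- meanZ2[names(meanZ1)]
  abs(meanZ2 - meanZ1) > threshold
}

#' Per-feature Mahalanobis attribution of an outlier subject
#'
#' For each feature, computes the univariate Mahalanobis distance of the
#' outlier subject to each group's distribution (the outlier excluded):
#' \eqn{d_G = |x - \bar x_G| / s_G}. Features whose distance difference
#' \eqn{\Delta = d_A - d_B} exceeds the threshold (default 0.3) are
#' attributed — the outlier resembles group B more than its own group A on
#' those features. Features with zero group standard deviation are skipped
#' and flagged.
#'
#' @param x an [ImmuneFeatureTable-class] or features x subjects matrix.
#' @param outlier subject (column) name of the outlier.
#' @param groupA,groupB character vectors of subject names defining the two
#'   reference distributions (the outlier is removed from both).
#' @param threshold attribution cutoff on \eqn{\Delta} (default 0.3).
#' @return A [S4Vectors::DataFrame] with \code{dA}, \code{dB}, \code{delta},
#'   \code{skipped} and \code{attributed} per feature.
#' @export
mahalanobisAttribution <- function(x, outlier, groupA, groupB,
                                   threshold = 0.3) {
  m <- if (is(x, "ImmuneFeatureTable")) featureValues(x) else as.matrix(x)
  stopifnot(outlier %in% colnames(m))
  groupA <- setdiff(groupA, outlier)
  groupB <- setdiff(groupB, outlier)
  if (length(groupA) < 3L || length(groupB) < 3L)
    stop("each group needs at least 3 subjects (outlier excluded)")
  xo <- m[, outlier]
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    a <- m[i, groupA]; b <- m[i, groupB]
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 || sb == 0) return(c(NA_real_, NA_real_, NA_real_, 1))
    dA <- abs(xo[i] - mean(a)) / sa
    dB <- abs(xo[i] - mean(b)) / sb
    c(dA, dB, dA - dB, 0)
  }, numeric(4)))
  DataFrame(
    feature = rownames(m) %||% paste0("feature", seq_len(nrow(m))),
    dA = res[, 1L], dB = res[, 2L], delta = res[, 3L],
    skipped = res[, 4L] == 1,
    attributed = !is.na(res[, 3L]) & res[, 3L] > threshold)
}
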