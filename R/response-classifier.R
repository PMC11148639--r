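# Patient stratification with random forests: out-of-bag hyperparameter
# tuning, ten-seed stability evaluation with rank-weighted Gini consensus,
# representative-seed selection, and Gini-threshold module selection.

.rangerFit <- function(df, mtry, minNodeSize, numTrees, seed,
                       importance = "none") {
  ranger::ranger(label ~ ., data = df, num.trees = numTrees, mtry = mtry,
                 min.node.size = minNodeSize, importance = importance,
                 seed = seed, num.threads = 1L)
}

.scoreFrame <- function(scores, labels) {
  m <- if (is(scores, "ModuleScores")) scoreMatrix(scores) else as.matrix(scores)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  if (min(table(labels)) < 2L) stop("need at least 2 subjects per class")
  if (anyNA(m)) stop("missing module scores")
  df <- as.data.frame(m)
  names(df) <- colnames(m)
  df$label <- labels
  df
}

#' Tune a random-forest classifier by out-of-bag error
#'
#' Trains one forest per grid point with a fixed tuning seed and records its
#' out-of-bag classification error; returns the OOB-minimal configuration,
#' breaking ties toward smaller \code{mtry} and then smaller minimum node
#' size. The default grid spans mtry in \code{ceiling(sqrt(p) * c(0.5, 1, 2))}
#' and minimum node sizes \code{1, 3, 5} with 1000 trees.
#'
#' @param scores a [ModuleScores-class] or subjects x modules matrix.
#' @param labels binary factor (or coercible) per subject.
#' @param grid optional data.frame with columns \code{mtry},
#'   \code{min.node.size}, \code{num.trees}.
#' @param tuningSeed seed used for every tuning fit.
#' @return A [TunedConfig-class].
#' @export
tuneForest <- function(scores, labels, grid = NULL, tuningSeed = 1L) {
  df <- .scoreFrame(scores, labels)
  p <- ncol(df) - 1L
  if (is.null(grid)) {
    mtries <- sort(unique(pmin(pmax(ceiling(sqrt(p) * c(0.5, 1, 2)), 1L), p)))
    grid <- expand.grid(mtry = mtries, min.node.size = c(1L, 3L, 5L),
                        num.trees = 1000L)
  }
  oob <- vapply(seq_len(nrow(grid)), function(i) {
    .rangerFit(df, grid$mtry[i], grid$min.node.size[i], grid$num.trees[i],
               seed = tuningSeed)$prediction.error
  }, numeric(1))
  ord <- order(oob, grid$mtry, grid$min.node.size)
  best <- ord[1L]
  new("TunedConfig", grid = grid, oobByGrid = oob,
      mtry = as.integer(grid$mtry[best]),
      minNodeSize = as.integer(grid$min.node.size[best]),
      numTrees = as.integer(grid$num.trees[best]),
      oobError = oob[best], tuningSeed = as.integer(tuningSeed))
}

#' Seed-stability evaluation and representative-seed selection
#'
#' Reruns the tuned forest across the given random seeds. Per seed, features
#' are ranked by Gini importance and each of the seed's top ten features
#' receives weight \code{11 - rank}; weights are summed across seeds into a
#' consensus score per feature. The representative seed is the one whose
#' top-ten list has the largest total consensus score (ties broken toward the
#' lowest seed value); its Gini vector is reported for downstream selection.
#' With fewer than ten features, the top \code{min(10, p)} are used.
#'
#' @param config a [TunedConfig-class].
#' @param scores a [ModuleScores-class] or subjects x modules matrix.
#' @param labels binary labels per subject.
#' @param seeds integer vector of seeds (the study procedure uses ten).
#' @param giniThreshold passed to [selectModules()]; \code{"auto"} (largest
#'   gap in the sorted Gini sequence) or a numeric cutoff.
#' @return A [ClassifierResult-class].
#' @export
stabilitySelect <- function(config, scores, labels, seeds = 1:10,
                            giniThreshold = "auto") {
  if (!length(seeds)) stop("empty seed list")
  seeds <- as.integer(seeds)
  df <- .scoreFrame(scores, labels)
  feats <- setdiff(names(df), "label")
  classCounts <- table(df$label)
  if (max(classCounts) / min(classCounts) > 2)
    warning("class imbalance exceeds 2:1; no reweighting is applied")
  topN <- min(10L, length(feats))

  giniBySeed <- matrix(0, nrow = length(seeds), ncol = length(feats),
                       dimnames = list(seeds, feats))
  oob <- numeric(length(seeds))
  topLists <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    fit <- .rangerFit(df, config@mtry, config@minNodeSize, config@numTrees,
                      seed = seeds[i], importance = "impurity")
    gini <- fit$variable.importance[feats]
    giniBySeed[i, ] <- gini
    oob[i] <- fit$prediction.error
    topLists[[i]] <- names(sort(gini, decreasing = TRUE))[seq_len(topN)]
  }
  consensus <- stats::setNames(numeric(length(feats)), feats)
  for (i in seq_along(seeds)) {
    w <- 11L - seq_len(topN)           # rank weight: 11 - rank, ranks 1..10
    consensus[topLists[[i]]] <- consensus[topLists[[i]]] + w
  }
  overlap <- vapply(topLists, function(tl) sum(consensus[tl]), numeric(1))
  repIdx <- order(-overlap, seeds)[1L]

  gini <- stats::setNames(giniBySeed[repIdx, ], feats)
  res <- new("ClassifierResult",
      perSeed = data.frame(seed = seeds, oob = oob),
      giniBySeed = giniBySeed, topLists = topLists, consensus = consensus,
      representativeSeed = seeds[repIdx], gini = gini,
      selectedFeatures = character(0), threshold = NA_real_, config = config)
  selectModules(res, threshold = giniThreshold)
}

#' Select modules above a Gini-importance threshold
#'
#' Returns the classifier result with \code{selectedFeatures} set to the
#' modules whose representative-seed Gini importance lies strictly above the
#' threshold. With \code{threshold = "auto"} the cutoff is placed at the
#' midpoint of the largest gap in the decreasing sorted Gini sequence (the
#' knee), and the numeric cutoff actually used is reported.
#'
#' @param result a [ClassifierResult-class].
#' @param threshold numeric Gini cutoff, or \code{"auto"}.
#' @return The updated [ClassifierResult-class]; access the selection with
#'   [selectedFeatures()].
#' @export
selectModules <- function(result, threshold = "auto") {
  gini <- result@gini
  if (identical(threshold, "auto")) {
    if (all(gini == 0)) stop("all importances are zero; 'auto' undefined")
    g <- sort(gini, decreasing = TRUE)
    if (length(g) < 2L) {
      threshold <- g[1L] / 2
    } else {
      gaps <- g[-length(g)] - g[-1L]
      i <- which.max(gaps)
      threshold <- (g[i] + g[i + 1L]) / 2
    }
  }
  result@threshold <- as.numeric(threshold)
  result@selectedFeatures <- names(gini)[gini > result@threshold]
  validObject(result)
  result
}

#' Compare timepoint parameters by tuned out-of-bag error
#'
#' Runs the full module + classifier pipeline (correlation, distance, Ward/
#' silhouette clustering, PC1 summaries, OOB tuning) independently per
#' timepoint parameter and tabulates the tuned OOB errors; the minimum-error
#' timepoint is flagged as the focus for downstream analysis.
#'
#' @param tables named list of fully imputed [ImmuneFeatureTable-class]
#'   objects (e.g. BL, C2, delta).
#' @param labels binary labels, named by subject or in table column order.
#' @param kRange passed to [clusterModules()].
#' @param tuningSeed passed to [tuneForest()].
#' @return data.frame with columns \code{timepoint}, \code{oob},
#'   \code{selected} (logical flag of the minimum), plus attribute
#'   \code{pipelines} holding each timepoint's module/classifier objects.
#' @export
compareTimepoints <- function(tables, labels, kRange = NULL, tuningSeed = 1L) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  pipelines <- lapply(tables, function(tab) {
    mod <- discoverModules(tab, kRange = kRange)
    lab <- if (!is.null(names(labels)))
      labels[colnames(tab)] else labels
    cfg <- tuneForest(mod$scores, lab, tuningSeed = tuningSeed)
    list(assignment = mod$assignment, scores = mod$scores, config = cfg)
  })
  oob <- vapply(pipelines, function(p) p$config@oobError, numeric(1))
  out <- data.frame(timepoint = names(tables), oob = unname(oob),
                    selected = seq_along(oob) == which.min(oob))
  attr(out, "pipelines") <- pipelines
  out
}
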