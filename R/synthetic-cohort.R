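# Synthetic cohorts with planted correlation-block structure, group effects,
# MCAR missingness, LOD censoring, and skewed TCR repertoires. All generators
# are driven by a single integer seed through derived sub-streams and leave the
# caller's RNG state untouched.

# derive a sub-seed for a named stream from the master seed (kept < 2^31)
.streamSeed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + offs) %% .Machine$integer.max)
}

#' Generate a synthetic multi-omic feature cohort
#'
#' Simulates a two-group cohort under a single-latent-factor model per module:
#' member features are \code{sqrt(rho) * factor + sqrt(1 - rho) * noise} with
#' all terms standard normal, giving expected pairwise correlation \code{rho}
#' within a module and 0 between modules. Modules listed in
#' \code{discriminativeModules} have their latent factor mean shifted by the
#' stated standardized amount in group 2. Missing entries are injected
#' completely at random at \code{missingRate}; per feature, values below the
#' empirical \code{lodRate} quantile are left-censored at that threshold
#' (mimicking limit-of-detection replacement already applied upstream).
#'
#' @param spec a [CohortSpec-class].
#' @param timepointParam timepoint tag stored on the table ("BL", "C2" or
#'   "delta"); purely annotational.
#' @return A list with \code{table} (an [ImmuneFeatureTable-class], features x
#'   subjects, possibly containing \code{NA}s) and \code{truth}
#'   (a [GroundTruth-class]).
#' @examples
#' spec <- CohortSpec(20, 8, 6, withinModuleRho = 0.8, nNoiseFeatures = 12,
#'                    discriminativeModules = c("1" = 1.5), seed = 1)
#' cohort <- generateFeatureCohort(spec)
#' dim(featureValues(cohort$table))
#' @export
generateFeatureCohort <- function(spec, timepointParam = "C2") {
  validObject(spec)
  nSub <- 2L * spec@nSubjectsPerGroup
  nMod <- spec@nModules
  fpm <- spec@featuresPerModule
  rho <- spec@withinModuleRho
  p <- nMod * fpm + spec@nNoiseFeatures

  group <- rep(c("group1", "group2"), each = spec@nSubjectsPerGroup)
  subjects <- sprintf("S%02d", seq_len(nSub))
  shifts <- numeric(nMod)
  if (length(spec@discriminativeModules))
    shifts[as.integer(names(spec@discriminativeModules))] <-
      spec@discriminativeModules

  mat <- withr::with_seed(.streamSeed(spec@seed, "features"), {
    out <- matrix(NA_real_, nrow = p, ncol = nSub)
    r <- 0L
    for (m in seq_len(nMod)) {
      f <- stats::rnorm(nSub) + shifts[m] * (group == "group2")
      for (j in seq_len(fpm)) {
        r <- r + 1L
        out[r, ] <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(nSub)
      }
    }
    if (spec@nNoiseFeatures > 0L)
      out[(r + 1L):p, ] <- matrix(stats::rnorm(spec@nNoiseFeatures * nSub),
                                  nrow = spec@nNoiseFeatures)
    out
  })

  moduleOfFeature <- c(rep(seq_len(nMod), each = fpm),
                       rep(0L, spec@nNoiseFeatures))
  featNames <- ifelse(moduleOfFeature > 0L,
                      sprintf("M%02d_f%d", moduleOfFeature,
                              stats::ave(moduleOfFeature, moduleOfFeature,
                                         FUN = seq_along)),
                      sprintf("noise_f%d", cumsum(moduleOfFeature == 0L)))
  dimnames(mat) <- list(featNames, subjects)

  if (spec@lodRate > 0) {
    lod <- apply(mat, 1L, stats::quantile, probs = spec@lodRate, names = FALSE)
    mat <- pmax(mat, lod)
  }
  if (spec@missingRate > 0) {
    mask <- withr::with_seed(.streamSeed(spec@seed, "missing"),
      matrix(stats::runif(length(mat)) < spec@missingRate, nrow = nrow(mat)))
    mat[mask] <- NA_real_
  }

  table <- new("ImmuneFeatureTable", SummarizedExperiment(
    assays = list(values = mat),
    rowData = DataFrame(omic = "serum", analyte = featNames,
                        statistic = "expression",
                        row.names = featNames),
    colData = DataFrame(subject = subjects, group = group,
                        row.names = subjects),
    metadata = list(timepointParam = timepointParam)))
  truth <- new("GroundTruth",
    moduleOfFeature = stats::setNames(as.integer(moduleOfFeature), featNames),
    discriminativeModuleIds =
      sort(unique(as.integer(names(spec@discriminativeModules)))),
    groupLabel = stats::setNames(group, subjects),
    neoplasticCloneId = NA_character_)
  list(table = table, truth = truth)
}

#' Generate a single-cell event-table fixture
#'
#' Builds a cell x marker intensity table with a cluster label column and
#' exactly the requested number of cells per cluster. Intensities are normal
#' around per-cluster marker means.
#'
#' @param nCellsPerCluster integer vector of cluster sizes (names become
#'   cluster labels; defaults to \code{cluster1..K}).
#' @param markerMeans clusters x markers numeric matrix of mean intensities
#'   (rownames matched to cluster labels; colnames are marker names).
#' @param noiseSd standard deviation of intensity noise.
#' @param sample sample identifier written into the \code{sample} column.
#' @param seed integer seed.
#' @return data.frame with columns \code{sample}, \code{cluster} and one
#'   column per marker.
#' @examples
#' mm <- matrix(c(0, 3), 2, 1, dimnames = list(NULL, "CD25"))
#' cells <- generateSingleCellFixture(c(14, 100), mm, seed = 1)
#' table(cells$cluster)
#' @export
generateSingleCellFixture <- function(nCellsPerCluster, markerMeans,
                                      noiseSd = 1, sample = "sample1",
                                      seed = 1L) {
  if (length(nCellsPerCluster) < 1L)
    stop("at least one cluster is required")
  markerMeans <- as.matrix(markerMeans)
  if (nrow(markerMeans) != length(nCellsPerCluster))
    stop("markerMeans needs one row per cluster")
  labels <- names(nCellsPerCluster)
  if (is.null(labels)) labels <- paste0("cluster", seq_along(nCellsPerCluster))
  markers <- colnames(markerMeans)
  if (is.null(markers)) markers <- paste0("marker", seq_len(ncol(markerMeans)))

  withr::with_seed(.streamSeed(seed, "cells"), {
    rows <- lapply(seq_along(nCellsPerCluster), function(i) {
      n <- nCellsPerCluster[i]
      if (n == 0L) return(NULL)
      vals <- matrix(stats::rnorm(n * length(markers), sd = noiseSd),
                     nrow = n, ncol = length(markers))
      vals <- sweep(vals, 2L, markerMeans[i, ], "+")
      colnames(vals) <- markers
      data.frame(sample = sample, cluster = labels[i], vals,
                 check.names = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic TCR repertoire
#'
#' Clone counts follow a skewed (Zipf-like) abundance distribution; every
#' clone receives at least one template. If \code{neoplasticCount} is given,
#' the first clone is designated dominant and receives exactly that count,
#' with the remaining templates distributed over the other clones.
#'
#' @param nClones number of distinct clonal families.
#' @param totalTemplates total template count (>= nClones).
#' @param neoplasticCount optional exact count for the designated dominant
#'   clone.
#' @param sample sample identifier.
#' @param seed integer seed.
#' @return A [Repertoire-class]; if \code{neoplasticCount} was given the
#'   planted clone's key is stored in \code{neoplasticClone()}.
#' @examples
#' rep <- generateRepertoire(50, totalTemplates = 2000, neoplasticCount = 100,
#'                           seed = 1)
#' identifyNeoplastic(rep)
#' @export
generateRepertoire <- function(nClones, totalTemplates,
                               neoplasticCount = NULL, sample = "sample1",
                               seed = 1L) {
  if (totalTemplates < nClones)
    stop("totalTemplates must be at least nClones")
  if (!is.null(neoplasticCount)) {
    if (neoplasticCount > totalTemplates)
      stop("neoplasticCount exceeds totalTemplates")
    if (nClones > 1L && totalTemplates - neoplasticCount < nClones - 1L)
      stop("too few templates left for the non-neoplastic clones")
  }

  withr::with_seed(.streamSeed(seed, "repertoire"), {
    vs <- sprintf("TRBV%d-%d", sample.int(30L, nClones, replace = TRUE),
                  sample.int(3L, nClones, replace = TRUE))
    js <- sprintf("TRBJ%d-%d", sample.int(2L, nClones, replace = TRUE),
                  sample.int(6L, nClones, replace = TRUE))
    aa <- c("A", "S", "G", "L", "V", "T", "R", "E", "Q", "Y")
    cdr3 <- vapply(seq_len(nClones), function(i)
      paste0("CASS", paste(sample(aa, 6L + i %% 4L, replace = TRUE),
                           collapse = ""), "F"), character(1))
    # de-duplicate clonal identities deterministically
    key <- paste(vs, js, cdr3, sep = "|")
    while (anyDuplicated(key)) {
      d <- which(duplicated(key))
      cdr3[d] <- paste0(cdr3[d], "Y")
      key <- paste(vs, js, cdr3, sep = "|")
    }

    counts <- if (is.null(neoplasticCount)) {
      .skewedCounts(nClones, totalTemplates)
    } else if (nClones == 1L) {
      neoplasticCount
    } else {
      # the designated clone must stay the single most abundant
      cap <- max(1L, neoplasticCount - 1L)
      rest <- totalTemplates - neoplasticCount
      if (rest > (nClones - 1L) * cap)
        stop("cannot keep the designated clone dominant: too many templates ",
             "left for the other clones")
      c(neoplasticCount, .cappedSkewedCounts(nClones - 1L, rest, cap))
    }
    clones <- data.frame(v_gene = vs, j_gene = js, cdr3_aa = cdr3,
                         templates = as.integer(counts))
    Repertoire(clones, sample = sample,
               neoplasticClone = if (is.null(neoplasticCount)) NA_character_
                                 else key[1L])
  })
}

# skewed counts with a per-clone ceiling; overflow is redistributed to the
# least abundant clones so the total is preserved exactly
.cappedSkewedCounts <- function(nClones, totalTemplates, cap) {
  counts <- .skewedCounts(nClones, totalTemplates)
  repeat {
    over <- counts > cap
    if (!any(over)) break
    excess <- sum(counts[over] - cap)
    counts[over] <- cap
    room <- which(counts < cap)
    room <- room[order(counts[room])]
    for (i in room) {
      take <- min(excess, cap - counts[i])
      counts[i] <- counts[i] + take
      excess <- excess - take
      if (excess == 0L) break
    }
    if (excess == 0L) break
  }
  counts
}

# one template per clone guaranteed; remainder multinomial with Zipf weights
.skewedCounts <- function(nClones, totalTemplates) {
  base <- rep(1L, nClones)
  extra <- totalTemplates - nClones
  if (extra > 0L) {
    w <- 1 / seq_len(nClones)
    base <- base + as.integer(stats::rmultinom(1L, extra, prob = w))
  }
  base
}

#' Generate a complete synthetic study (features + repertoires)
#'
#' Convenience wrapper used by the pipeline's \code{simulate} stage: one
#' feature cohort per timepoint parameter plus a pair of blood repertoires per
#' subject-group (leukemic repertoires receive a planted dominant clone).
#'
#' @param spec a [CohortSpec-class].
#' @param timepoints character vector of timepoint parameters to emit.
#' @param signalTimepoint the timepoint that carries the planted group effect;
#'   other timepoints are generated without it.
#' @return list with \code{tables} (named list of cohort lists per timepoint)
#'   and \code{repertoires} (list of [Repertoire-class]).
#' @export
generateStudy <- function(spec, timepoints = c("BL", "C2"),
                          signalTimepoint = "C2") {
  tables <- lapply(timepoints, function(tp) {
    s <- spec
    if (tp != signalTimepoint) s@discriminativeModules <- numeric(0)
    s@seed <- .streamSeed(spec@seed, paste0("tp-", tp))
    generateFeatureCohort(s, timepointParam = tp)
  })
  names(tables) <- timepoints
  reps <- list(
    leukemic = generateRepertoire(200L, totalTemplates = 5000L,
                                  neoplasticCount = 2500L, sample = "leukemic",
                                  seed = .streamSeed(spec@seed, "rep-leuk")),
    polyclonal = generateRepertoire(200L, totalTemplates = 5000L,
                                    sample = "polyclonal",
                                    seed = .streamSeed(spec@seed, "rep-poly")))
  list(tables = tables, repertoires = reps)
}
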