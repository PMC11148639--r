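#' @name accessors
#' @title Accessors for immunoModules classes
#' @description Slot accessors for the package's S4 classes; prefer these over
#'   direct slot access.
#' @param x an object of the documented class.
#' @param object an object of the documented class.
#' @return The accessed component; see each method.
NULL

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @describeIn accessors feature matrix (features x subjects) of an
#'   [ImmuneFeatureTable-class].
#' @export
setMethod("featureValues", "ImmuneFeatureTable", function(x) assay(x, "values"))

#' @rdname accessors
#' @export
setGeneric("imputedMask", function(x) standardGeneric("imputedMask"))

#' @describeIn accessors logical mask of imputed cells (or NULL before
#'   imputation).
#' @export
setMethod("imputedMask", "ImmuneFeatureTable", function(x) {
  if ("imputed" %in% names(assays(x))) assay(x, "imputed") else NULL
})

#' @rdname accessors
#' @export
setGeneric("timepointParam", function(x) standardGeneric("timepointParam"))

#' @describeIn accessors timepoint parameter ("BL", "C2" or "delta").
#' @export
setMethod("timepointParam", "ImmuneFeatureTable",
          function(x) metadata(x)$timepointParam)

#' @rdname accessors
#' @export
setGeneric("moduleOf", function(x) standardGeneric("moduleOf"))

#' @describeIn accessors named integer feature -> module map of a
#'   [ModuleAssignment-class].
#' @export
setMethod("moduleOf", "ModuleAssignment", function(x) x@moduleOfFeature)

#' @describeIn accessors planted feature -> module map of a
#'   [GroundTruth-class] (0 = noise).
#' @export
setMethod("moduleOf", "GroundTruth", function(x) x@moduleOfFeature)

#' @rdname accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @describeIn accessors silhouette-maximal module count.
#' @export
setMethod("selectedK", "ModuleAssignment", function(x) x@kSelected)

#' @rdname accessors
#' @export
setGeneric("silhouetteTrace", function(x) standardGeneric("silhouetteTrace"))

#' @describeIn accessors named numeric of mean silhouette width per k.
#' @export
setMethod("silhouetteTrace", "ModuleAssignment", function(x) x@silhouetteByK)

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @describeIn accessors subjects x modules PC1 score matrix of a
#'   [ModuleScores-class].
#' @export
setMethod("scoreMatrix", "ModuleScores", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @describeIn accessors per-module PC1 variance explained.
#' @export
setMethod("varianceExplained", "ModuleScores", function(x) x@varianceExplained)

#' @rdname accessors
#' @export
setGeneric("moduleLoadings", function(x) standardGeneric("moduleLoadings"))

#' @describeIn accessors list of per-module PC1 loading vectors.
#' @export
setMethod("moduleLoadings", "ModuleScores", function(x) x@loadings)

#' @rdname accessors
#' @export
setGeneric("giniImportance", function(x) standardGeneric("giniImportance"))

#' @describeIn accessors representative-seed Gini importance vector of a
#'   [ClassifierResult-class].
#' @export
setMethod("giniImportance", "ClassifierResult", function(x) x@gini)

#' @rdname accessors
#' @export
setGeneric("representativeSeed", function(x) standardGeneric("representativeSeed"))

#' @describeIn accessors the representative seed.
#' @export
setMethod("representativeSeed", "ClassifierResult", function(x) x@representativeSeed)

#' @rdname accessors
#' @export
setGeneric("consensusRanking", function(x) standardGeneric("consensusRanking"))

#' @describeIn accessors named consensus rank-weight sums, decreasing.
#' @export
setMethod("consensusRanking", "ClassifierResult",
          function(x) sort(x@consensus, decreasing = TRUE))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @describeIn accessors features (modules) above the Gini threshold.
#' @export
setMethod("selectedFeatures", "ClassifierResult", function(x) x@selectedFeatures)

#' @rdname accessors
#' @export
setGeneric("oobError", function(x) standardGeneric("oobError"))

#' @describeIn accessors chosen out-of-bag error of a [TunedConfig-class].
#' @export
setMethod("oobError", "TunedConfig", function(x) x@oobError)

#' @describeIn accessors per-seed out-of-bag errors of a
#'   [ClassifierResult-class].
#' @export
setMethod("oobError", "ClassifierResult", function(x) {
  stats::setNames(x@perSeed$oob, x@perSeed$seed)
})

#' @rdname accessors
#' @export
setGeneric("cloneFrequencies", function(x) standardGeneric("cloneFrequencies"))

#' @describeIn accessors named clone frequencies p_i = count_i / total of a
#'   [Repertoire-class].
#' @export
setMethod("cloneFrequencies", "Repertoire", function(x) {
  stats::setNames(x@clones$templates / sum(x@clones$templates),
                  cloneKeys(x@clones))
})

#' @rdname accessors
#' @export
setGeneric("totalTemplates", function(x) standardGeneric("totalTemplates"))

#' @describeIn accessors total template count of a [Repertoire-class].
#' @export
setMethod("totalTemplates", "Repertoire", function(x) sum(x@clones$templates))

#' @rdname accessors
#' @export
setGeneric("neoplasticClone", function(x) standardGeneric("neoplasticClone"))

#' @describeIn accessors annotated neoplastic clone key (or NA).
#' @export
setMethod("neoplasticClone", "Repertoire", function(x) x@neoplasticClone)

#' Clone keys
#'
#' Canonical clonal-family identifier: \code{"V|J|CDR3"}.
#' @param clones data.frame with v_gene, j_gene, cdr3_aa columns.
#' @return character vector of keys.
#' @export
cloneKeys <- function(clones) {
  paste(clones$v_gene, clones$j_gene, clones$cdr3_aa, sep = "|")
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", 2L * object@nSubjectsPerGroup, "subjects (2 groups),",
      object@nModules, "modules x", object@featuresPerModule, "features +",
      object@nNoiseFeatures, "noise features\n")
  cat("  within-module rho:", object@withinModuleRho,
      " missing rate:", object@missingRate,
      " LOD rate:", object@lodRate, "\n")
  if (length(object@discriminativeModules))
    cat("  discriminative modules:",
        paste0(names(object@discriminativeModules), " (shift ",
               object@discriminativeModules, ")", collapse = ", "), "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "ModuleAssignment", function(object) {
  cat("ModuleAssignment:", length(object@moduleOfFeature), "features in",
      object@kSelected, "modules (silhouette-selected)\n")
  sizes <- table(object@moduleOfFeature)
  cat("  module sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  cat("  mean silhouette at k =", object@kSelected, ":",
      round(object@silhouetteByK[[as.character(object@kSelected)]], 3), "\n")
})

setMethod("show", "ModuleScores", function(object) {
  cat("ModuleScores:", nrow(object@scores), "subjects x",
      ncol(object@scores), "modules (PC1 summaries)\n")
  cat("  variance explained:",
      paste(round(object@varianceExplained, 2), collapse = ", "), "\n")
})

setMethod("show", "TunedConfig", function(object) {
  cat("TunedConfig: mtry =", object@mtry, ", min node size =", object@minNodeSize,
      ", trees =", object@numTrees, "\n")
  cat("  OOB error:", round(object@oobError, 4), "(grid of",
      nrow(object@grid), "points)\n")
})

setMethod("show", "ClassifierResult", function(object) {
  cat("ClassifierResult:", nrow(object@perSeed), "seeds, representative seed",
      object@representativeSeed, "\n")
  cat("  per-seed OOB error:",
      paste(round(object@perSeed$oob, 3), collapse = ", "), "\n")
  cat("  Gini threshold:", signif(object@threshold, 4), "->",
      length(object@selectedFeatures), "selected:",
      paste(object@selectedFeatures, collapse = ", "), "\n")
})

setMethod("show", "Repertoire", function(object) {
  cat("Repertoire", object@sample, ":", nrow(object@clones), "clones,",
      sum(object@clones$templates), "templates\n")
  if (!is.na(object@neoplasticClone))
    cat("  neoplastic clone:", object@neoplasticClone, "\n")
})

setMethod("show", "ZMatrix", function(object) {
  cat("ZMatrix:", nrow(object@z), "subjects x", ncol(object@z), "features\n")
})
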