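#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Specification of a synthetic multi-omic cohort
#'
#' Describes the generative model for a two-group cohort whose features are
#' organised into correlated blocks ("planted modules"), optionally with
#' group-discriminative modules, completely-at-random missingness and
#' limit-of-detection censoring. The generative model is a single-factor
#' model per module: each member feature equals
#' \code{sqrt(rho) * factor + sqrt(1 - rho) * noise} with all terms standard
#' normal, so the expected pairwise correlation of two members is \code{rho}.
#'
#' @slot nSubjectsPerGroup integer, subjects per group (two groups, balanced).
#' @slot nModules integer, number of planted modules.
#' @slot featuresPerModule integer, features in each planted module.
#' @slot withinModuleRho numeric in [0, 1), target within-module correlation.
#' @slot nNoiseFeatures integer, independent standard-normal features.
#' @slot discriminativeModules named numeric; names are planted module indices
#'   and values are standardized mean shifts (delta mu / sigma) applied to the
#'   module's latent factor between the two groups.
#' @slot missingRate numeric in [0, 1), fraction of entries set missing (MCAR).
#' @slot lodRate numeric in [0, 1), per-feature fraction left-censored at the
#'   feature's empirical \code{lodRate} quantile.
#' @slot seed integer driving all sub-generators.
#'
#' @seealso [generateFeatureCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nSubjectsPerGroup = "integer",
    nModules = "integer",
    featuresPerModule = "integer",
    withinModuleRho = "numeric",
    nNoiseFeatures = "integer",
    discriminativeModules = "numeric",
    missingRate = "numeric",
    lodRate = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjectsPerGroup < 1L) msg <- c(msg, "nSubjectsPerGroup must be >= 1")
  if (object@nModules < 1L) msg <- c(msg, "nModules must be >= 1")
  if (object@featuresPerModule < 1L) msg <- c(msg, "featuresPerModule must be >= 1")
  if (object@nNoiseFeatures < 0L) msg <- c(msg, "nNoiseFeatures must be >= 0")
  if (object@withinModuleRho < 0 || object@withinModuleRho >= 1)
    msg <- c(msg, "withinModuleRho must lie in [0, 1)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (object@lodRate < 0 || object@lodRate >= 1)
    msg <- c(msg, "lodRate must lie in [0, 1)")
  if (length(object@discriminativeModules)) {
    idx <- as.integer(names(object@discriminativeModules))
    if (anyNA(idx) || any(idx < 1L) || any(idx > object@nModules))
      msg <- c(msg, "discriminativeModules names must be module indices in 1..nModules")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' @param nSubjectsPerGroup subjects per group (two balanced groups).
#' @param nModules number of planted feature modules.
#' @param featuresPerModule features per planted module.
#' @param withinModuleRho target within-module correlation in [0, 1).
#' @param nNoiseFeatures number of unstructured noise features.
#' @param discriminativeModules named numeric vector of standardized mean
#'   shifts; names are module indices (e.g. \code{c("1" = 1.5)}).
#' @param missingRate fraction of entries made missing, completely at random.
#' @param lodRate per-feature fraction left-censored at the limit of detection.
#' @param seed integer seed.
#' @return A [CohortSpec-class] object.
#' @examples
#' CohortSpec(20, nModules = 8, featuresPerModule = 6, withinModuleRho = 0.8,
#'            nNoiseFeatures = 12, discriminativeModules = c("1" = 1.5), seed = 1)
#' @export
CohortSpec <- function(nSubjectsPerGroup, nModules, featuresPerModule,
                       withinModuleRho = 0.8, nNoiseFeatures = 0L,
                       discriminativeModules = numeric(0),
                       missingRate = 0, lodRate = 0, seed = 1L) {
  if (length(discriminativeModules) && is.null(names(discriminativeModules)))
    stop("discriminativeModules must be named by module index")
  new("CohortSpec",
    nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
    nModules = as.integer(nModules),
    featuresPerModule = as.integer(featuresPerModule),
    withinModuleRho = as.numeric(withinModuleRho),
    nNoiseFeatures = as.integer(nNoiseFeatures),
    discriminativeModules = discriminativeModules,
    missingRate = as.numeric(missingRate),
    lodRate = as.numeric(lodRate),
    seed = as.integer(seed))
}

#' Ground truth of a synthetic cohort
#'
#' @slot moduleOfFeature named integer; module index per feature, 0 for noise.
#' @slot discriminativeModuleIds integer, modules carrying a group effect.
#' @slot groupLabel named character, group per subject.
#' @slot neoplasticCloneId character, planted dominant clone key (or NA).
#' @export
setClass("GroundTruth",
  representation(
    moduleOfFeature = "integer",
    discriminativeModuleIds = "integer",
    groupLabel = "character",
    neoplasticCloneId = "character"
  )
)

#' Harmonized immune feature table
#'
#' A \linkS4class{SummarizedExperiment} with features in rows and subjects in
#' columns. Assay \code{"values"} holds the feature matrix; assay
#' \code{"imputed"} is a logical mask marking every cell filled by column-mean
#' imputation. \code{rowData} records per-feature provenance (omic, analyte,
#' statistic kind, zero-variance flag); \code{metadata()$timepointParam} is
#' one of \code{"BL"}, \code{"C2"}, \code{"delta"}.
#'
#' @seealso [assembleFeatures()], [featureValues()]
#' @export
setClass("ImmuneFeatureTable", contains = "SummarizedExperiment")

setValidity("ImmuneFeatureTable", function(object) {
  msg <- character()
  if (!"values" %in% names(assays(object)))
    msg <- c(msg, "assay 'values' is required")
  tp <- metadata(object)$timepointParam
  if (!is.null(tp) && !tp %in% c("BL", "C2", "delta"))
    msg <- c(msg, "timepointParam must be one of 'BL', 'C2', 'delta'")
  if ("imputed" %in% names(assays(object))) {
    if (!is.logical(assay(object, "imputed")))
      msg <- c(msg, "assay 'imputed' must be logical")
    if (anyNA(assay(object, "values")))
      msg <- c(msg, "imputed tables must not contain missing values")
  }
  if (length(msg)) msg else TRUE
})

#' One omic block prior to assembly
#'
#' Holds one omic's analyte-by-sample matrix together with per-sample subject,
#' trial and timepoint annotations and per-analyte metadata. Samples are
#' subject-timepoint pairs; missing measurements are explicit \code{NA}s.
#'
#' @slot values numeric matrix, analytes x samples.
#' @slot omic one of \code{"serum"}, \code{"tumor_rna"},
#'   \code{"single_cell_summary"}.
#' @slot analyteData [S4Vectors::DataFrame] of per-analyte metadata
#'   (panel/gene or cluster, marker, statistic).
#' @slot subject,trial,timepoint character vectors, one entry per sample
#'   (column).
#' @export
setClass("OmicBlock",
  representation(
    values = "matrix",
    omic = "character",
    analyteData = "DataFrame",
    subject = "character",
    trial = "character",
    timepoint = "character"
  )
)

setValidity("OmicBlock", function(object) {
  msg <- character()
  n <- ncol(object@values)
  if (length(object@subject) != n || length(object@trial) != n ||
      length(object@timepoint) != n)
    msg <- c(msg, "subject, trial and timepoint must have one entry per sample")
  if (!object@omic %in% c("serum", "tumor_rna", "single_cell_summary"))
    msg <- c(msg, "omic must be 'serum', 'tumor_rna' or 'single_cell_summary'")
  if (nrow(object@analyteData) != nrow(object@values))
    msg <- c(msg, "analyteData must have one row per analyte")
  if (anyDuplicated(paste(object@subject, object@timepoint)))
    msg <- c(msg, "duplicated (subject, timepoint) samples")
  v <- object@values
  if (any(is.infinite(v)))
    msg <- c(msg, "values must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicBlock
#'
#' @param values analytes x samples numeric matrix (rownames = analytes).
#' @param omic omic label: "serum", "tumor_rna" or "single_cell_summary".
#' @param subject,trial,timepoint per-sample annotations (recycled if length 1).
#' @param analyteData optional per-analyte [S4Vectors::DataFrame].
#' @return An [OmicBlock-class].
#' @export
OmicBlock <- function(values, omic, subject, trial = "trial1", timepoint = "BL",
                      analyteData = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("analyte", seq_len(nrow(values)))
  n <- ncol(values)
  if (is.null(analyteData))
    analyteData <- DataFrame(analyte = rownames(values))
  new("OmicBlock", values = values, omic = omic,
      analyteData = analyteData,
      subject = rep_len(as.character(subject), n),
      trial = rep_len(as.character(trial), n),
      timepoint = rep_len(as.character(timepoint), n))
}

#' Partition of features into immune modules
#'
#' @slot moduleOfFeature named integer partition map (feature -> module id).
#' @slot kSelected integer, silhouette-maximal number of modules.
#' @slot silhouetteByK named numeric, mean silhouette width per candidate k.
#' @slot linkage the \code{hclust} tree (Ward on the precomputed distance).
#' @slot constantFeatures character, zero-variance features (correlation
#'   defined as 0 against everything).
#' @export
setClass("ModuleAssignment",
  representation(
    moduleOfFeature = "integer",
    kSelected = "integer",
    silhouetteByK = "numeric",
    linkage = "ANY",
    constantFeatures = "character"
  )
)

setValidity("ModuleAssignment", function(object) {
  msg <- character()
  if (anyNA(object@moduleOfFeature))
    msg <- c(msg, "every feature must be assigned a module")
  ks <- as.integer(names(object@silhouetteByK))
  best <- max(object@silhouetteByK)
  if (!object@kSelected %in% ks)
    msg <- c(msg, "kSelected must come from the searched k range")
  else if (object@silhouetteByK[[as.character(object@kSelected)]] < best - 1e-12)
    msg <- c(msg, "kSelected must maximize the mean silhouette")
  if (length(msg)) msg else TRUE
})

#' Per-subject module summaries (PC1 scores)
#'
#' @slot scores subjects x modules matrix of first-principal-component scores
#'   of each module's Z-scored member features.
#' @slot loadings list of per-module loading vectors.
#' @slot varianceExplained numeric in [0, 1] per module.
#' @slot orientation numeric of +/-1 per module; sign applied so PC1
#'   correlates non-negatively with the mean member Z-score.
#' @export
setClass("ModuleScores",
  representation(
    scores = "matrix",
    loadings = "list",
    varianceExplained = "numeric",
    orientation = "numeric"
  )
)

setValidity("ModuleScores", function(object) {
  msg <- character()
  if (ncol(object@scores) != length(object@varianceExplained))
    msg <- c(msg, "one varianceExplained entry per module required")
  if (any(object@varianceExplained < -1e-9 | object@varianceExplained > 1 + 1e-9))
    msg <- c(msg, "varianceExplained must lie in [0, 1]")
  cm <- colMeans(object@scores)
  if (any(abs(cm) > 1e-8))
    msg <- c(msg, "module scores must have zero mean over subjects")
  if (length(msg)) msg else TRUE
})

#' Tuned random-forest configuration
#'
#' @slot grid data.frame of searched hyperparameter combinations
#'   (\code{mtry}, \code{min.node.size}, \code{num.trees}).
#' @slot oobByGrid numeric, out-of-bag error per grid point.
#' @slot mtry,minNodeSize,numTrees chosen values (OOB-minimal; ties broken
#'   toward smaller mtry, then smaller node size).
#' @slot oobError the chosen configuration's out-of-bag error.
#' @slot tuningSeed seed used for all tuning fits.
#' @export
setClass("TunedConfig",
  representation(
    grid = "data.frame",
    oobByGrid = "numeric",
    mtry = "integer",
    minNodeSize = "integer",
    numTrees = "integer",
    oobError = "numeric",
    tuningSeed = "integer"
  )
)

setValidity("TunedConfig", function(object) {
  if (object@oobError > min(object@oobByGrid) + 1e-12)
    "chosen configuration must minimize out-of-bag error" else TRUE
})

#' Seed-stability random-forest result
#'
#' @slot perSeed data.frame with one row per seed: seed and OOB error.
#' @slot giniBySeed seeds x features matrix of Gini importances.
#' @slot topLists list of each seed's top-ranked feature names.
#' @slot consensus named numeric, rank-weight sums across seeds.
#' @slot representativeSeed the seed whose top list best matches the consensus.
#' @slot gini named numeric, the representative seed's Gini importances.
#' @slot selectedFeatures character, features above the Gini threshold.
#' @slot threshold numeric Gini cutoff actually applied.
#' @slot config the [TunedConfig-class] used.
#' @export
setClass("ClassifierResult",
  representation(
    perSeed = "data.frame",
    giniBySeed = "matrix",
    topLists = "list",
    consensus = "numeric",
    representativeSeed = "integer",
    gini = "numeric",
    selectedFeatures = "character",
    threshold = "numeric",
    config = "ANY"
  )
)

setValidity("ClassifierResult", function(object) {
  msg <- character()
  if (!object@representativeSeed %in% object@perSeed$seed)
    msg <- c(msg, "representativeSeed must be one of the run seeds")
  if (length(object@threshold) == 1L && !is.na(object@threshold)) {
    above <- names(object@gini)[object@gini > object@threshold]
    if (!setequal(above, object@selectedFeatures))
      msg <- c(msg, "selectedFeatures must be the features with Gini above threshold")
  }
  if (length(msg)) msg else TRUE
})

#' TCR repertoire for one sample
#'
#' Clonal families are identified by identical V gene, J gene and CDR3
#' amino-acid sequence; non-productive CDR3s are assumed filtered upstream.
#'
#' @slot clones data.frame with columns \code{v_gene}, \code{j_gene},
#'   \code{cdr3_aa}, \code{templates} (positive integer counts).
#' @slot sample sample identifier.
#' @slot neoplasticClone key of the annotated neoplastic clone, or
#'   \code{NA_character_}.
#' @seealso [identifyNeoplastic()], [giniSimpson()], [morisitaHorn()]
#' @export
setClass("Repertoire",
  representation(
    clones = "data.frame",
    sample = "character",
    neoplasticClone = "character"
  )
)

setValidity("Repertoire", function(object) {
  msg <- character()
  need <- c("v_gene", "j_gene", "cdr3_aa", "templates")
  if (!all(need %in% names(object@clones)))
    msg <- c(msg, "clones needs columns v_gene, j_gene, cdr3_aa, templates")
  else {
    tmpl <- object@clones$templates
    if (any(tmpl <= 0) || any(tmpl != round(tmpl)))
      msg <- c(msg, "template counts must be positive integers")
    if (anyDuplicated(cloneKeys(object@clones)))
      msg <- c(msg, "duplicated clonal families (same V, J, CDR3)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Repertoire
#'
#' @param clones data.frame with columns \code{v_gene}, \code{j_gene},
#'   \code{cdr3_aa} and \code{templates}.
#' @param sample sample identifier.
#' @param neoplasticClone optional clone key ("V|J|CDR3") of the neoplastic
#'   clone.
#' @return A [Repertoire-class].
#' @examples
#' rep <- Repertoire(data.frame(v_gene = "TRBV9", j_gene = "TRBJ1-1",
#'                              cdr3_aa = "CASSF", templates = 80))
#' totalTemplates(rep)
#' @export
Repertoire <- function(clones, sample = "sample1", neoplasticClone = NA_character_) {
  new("Repertoire", clones = as.data.frame(clones), sample = sample,
      neoplasticClone = neoplasticClone)
}

#' Z-score stratification matrix
#'
#' @slot z subjects x features matrix of column-wise Z scores.
#' @slot subjectOrder integer, dendrogram leaf order of subjects (Ward on
#'   Euclidean distances between Z rows).
#' @slot groupLabel named character, group per subject.
#' @slot groupMeanZ matrix, per-group mean Z per feature (groups x features).
#' @export
setClass("ZMatrix",
  representation(
    z = "matrix",
    subjectOrder = "integer",
    groupLabel = "character",
    groupMeanZ = "matrix"
  )
)

setValidity("ZMatrix", function(object) {
  ok <- apply(object@z, 2L, function(col) {
    (abs(mean(col)) < 1e-8) && (abs(stats::sd(col) - 1) < 1e-8 || all(col == 0))
  })
  if (!all(ok)) "each Z column must have mean 0 and unit variance (or be all zero)"
  else TRUE
})
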