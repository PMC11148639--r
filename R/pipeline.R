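# End-to-end orchestration: simulate (or load) -> assemble -> modules ->
# classify -> differential stats -> attribution -> TCR metrics, with one
# config, TSV outputs per stage and a reproducibility manifest.

#' Default pipeline configuration
#'
#' Every study threshold is surfaced as a named key with its default:
#' significance rule \code{q < 0.1} or (\code{p < 0.05} and \code{|ES| > 1});
#' delta-Mahalanobis attribution cutoff 0.3; substantial Z-shift cutoff 0.5;
#' neoplastic clone minimum 75 templates; minimum 15 cells for per-cluster
#' marker statistics; differential-clone cutoff \code{q < 0.05}; Gini module
#' threshold \code{"auto"} (largest gap).
#'
#' @return nested list of defaults; override any entry via the \code{config}
#'   argument of [runPipeline()].
#' @export
defaultConfig <- function() {
  list(
    simulate = list(
      nSubjectsPerGroup = 20L, nModules = 8L, featuresPerModule = 6L,
      withinModuleRho = 0.8, nNoiseFeatures = 12L,
      discriminativeModules = c("1" = 1.5),
      missingRate = 0.02, lodRate = 0.05),
    timepoints = c("BL", "C2"),
    signalTimepoint = "C2",
    classify = list(seeds = 10L, giniThreshold = "auto"),
    thresholds = list(q = 0.1, p = 0.05, es = 1, mahalanobis = 0.3,
                      zShift = 0.5, neoplasticMinCount = 75L, minCells = 15L,
                      cloneQ = 0.05)
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write module-discovery outputs as delimited text
#'
#' @param assignment a [ModuleAssignment-class].
#' @param scores a [ModuleScores-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeModuleOutputs <- function(assignment, scores, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  part <- moduleOf(assignment)
  paths <- c(
    .writeTsv(data.frame(feature = names(part), module = unname(part)),
              file.path(dir, "module_assignment.tsv")),
    .writeTsv(data.frame(k = as.integer(names(silhouetteTrace(assignment))),
                         mean_silhouette = unname(silhouetteTrace(assignment))),
              file.path(dir, "silhouette_curve.tsv")),
    .writeTsv(data.frame(subject = rownames(scoreMatrix(scores)),
                         scoreMatrix(scores), check.names = FALSE),
              file.path(dir, "module_scores.tsv")),
    .writeTsv(do.call(rbind, lapply(names(moduleLoadings(scores)), function(mn) {
      l <- moduleLoadings(scores)[[mn]]
      data.frame(module = mn, feature = names(l), loading = unname(l))
    })), file.path(dir, "module_loadings.tsv")))
  invisible(paths)
}

#' Write classifier outputs as delimited text and JSON
#'
#' @param result a [ClassifierResult-class].
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
writeClassifierOutputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cons <- consensusRanking(result)
  paths <- c(
    .writeTsv(cbind(result@perSeed,
                    as.data.frame(result@giniBySeed, check.names = FALSE)),
              file.path(dir, "per_seed_oob_gini.tsv")),
    .writeTsv(data.frame(feature = names(cons), consensus_weight = unname(cons)),
              file.path(dir, "consensus_ranking.tsv")))
  sel <- file.path(dir, "selected_modules.json")
  jsonlite::write_json(
    list(representative_seed = representativeSeed(result),
         gini_threshold = result@threshold,
         selected_modules = selectedFeatures(result)),
    sel, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sel))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> assemble/impute -> module discovery -> classifier ->
#' differential statistics -> Mahalanobis attribution -> TCR metrics under a
#' single configuration, writing each stage's outputs as delimited text plus
#' a JSON manifest (config, config hash, seed, package version) that
#' suffices to reproduce the run: identical manifests yield identical module
#' partitions, consensus rankings and representative-seed selections.
#'
#' @param config list of overrides merged onto [defaultConfig()], or a path
#'   to a YAML file of such overrides.
#' @param outDir output directory.
#' @param seed master integer seed for every source of randomness.
#' @return invisibly, a list with the per-timepoint pipeline objects, the
#'   comparison table, differential results, attribution, TCR summaries and
#'   the manifest.
#' @export
runPipeline <- function(config = list(), outDir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$simulate$discriminativeModules))
    config$simulate$discriminativeModules <-
      unlist(config$simulate$discriminativeModules)
  cfg <- .mergeConfig(defaultConfig(), config)
  if (is.null(cfg$labels)) cfg$labels <- "group"
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  sim <- cfg$simulate
  spec <- CohortSpec(sim$nSubjectsPerGroup, sim$nModules, sim$featuresPerModule,
                     withinModuleRho = sim$withinModuleRho,
                     nNoiseFeatures = sim$nNoiseFeatures,
                     discriminativeModules = sim$discriminativeModules,
                     missingRate = sim$missingRate, lodRate = sim$lodRate,
                     seed = seed)
  study <- generateStudy(spec, timepoints = cfg$timepoints,
                         signalTimepoint = cfg$signalTimepoint)

  tables <- lapply(study$tables, function(co) imputeColumnMean(co$table))
  truth <- study$tables[[1L]]$truth
  labels <- truth@groupLabel
  for (tp in names(tables))
    .writeTsv(data.frame(feature = rownames(featureValues(tables[[tp]])),
                         featureValues(tables[[tp]]), check.names = FALSE),
              file.path(outDir, paste0("features_", tp, ".tsv")))

  cmp <- compareTimepoints(tables, labels, tuningSeed = seed)
  .writeTsv(cmp, file.path(outDir, "timepoint_oob.tsv"))
  pipes <- attr(cmp, "pipelines")
  focus <- cmp$timepoint[cmp$selected][1L]

  classifySeeds <- seq_len(cfg$classify$seeds) + seed
  results <- list()
  for (tp in names(tables)) {
    pp <- pipes[[tp]]
    res <- stabilitySelect(pp$config, pp$scores, labels[colnames(tables[[tp]])],
                           seeds = classifySeeds,
                           giniThreshold = cfg$classify$giniThreshold)
    tpDir <- file.path(outDir, tp)
    writeModuleOutputs(pp$assignment, pp$scores, tpDir)
    writeClassifierOutputs(res, tpDir)

    diff <- differentialDistribution(tables[[tp]], labels[colnames(tables[[tp]])],
                                     qCut = cfg$thresholds$q,
                                     pCut = cfg$thresholds$p,
                                     esCut = cfg$thresholds$es)
    .writeTsv(as.data.frame(diff), file.path(tpDir, "differential_features.tsv"))

    selFeats <- names(moduleOf(pp$assignment))[
      moduleOf(pp$assignment) %in%
        as.integer(sub("module", "", selectedFeatures(res)))]
    strat <- NULL
    if (length(selFeats) >= 2L) {
      strat <- zscoreStratify(tables[[tp]], selFeats,
                              labels[colnames(tables[[tp]])])
      .writeTsv(data.frame(subject = rownames(strat@z)[strat@subjectOrder],
                           group = strat@groupLabel[strat@subjectOrder],
                           strat@z[strat@subjectOrder, , drop = FALSE],
                           check.names = FALSE),
                file.path(tpDir, "z_stratification.tsv"))
    }
    results[[tp]] <- list(classifier = res, differential = diff,
                          stratification = strat)
  }

  # TCR stage on the simulated blood repertoires
  reps <- study$repertoires
  tcr <- data.frame(
    sample = vapply(reps, function(r) r@sample, character(1)),
    n_clones = vapply(reps, function(r) nrow(r@clones), integer(1)),
    total_templates = vapply(reps, totalTemplates, numeric(1)),
    neoplastic = vapply(reps, function(r)
      identifyNeoplastic(r, cfg$thresholds$neoplasticMinCount) %||%
        NA_character_, character(1)),
    gini_simpson = vapply(reps, giniSimpson, numeric(1)))
  tcr$gini_simpson_wo_neoplastic <- vapply(seq_along(reps), function(i) {
    if (is.na(tcr$neoplastic[i])) return(tcr$gini_simpson[i])
    giniSimpson(reps[[i]], exclude = tcr$neoplastic[i])
  }, numeric(1))
  .writeTsv(tcr, file.path(outDir, "tcr_summary.tsv"))
  mh <- morisitaHorn(reps[[1L]], reps[[2L]])
  dc <- differentialClones(reps[[1L]], reps[[2L]], qCut = cfg$thresholds$cloneQ)
  .writeTsv(as.data.frame(utils::head(dc, 100L)),
            file.path(outDir, "differential_clones.tsv"))

  manifest <- list(
    package = "immunoModules",
    version = as.character(utils::packageVersion("immunoModules")),
    seed = seed,
    classify_seeds = classifySeeds,
    config = cfg,
    config_hash = .configHash(cfg),
    focus_timepoint = focus,
    morisita_horn_blood = mh)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(tables = tables, truth = truth, comparison = cmp,
                 results = results, tcr = tcr, differentialClones = dc,
                 manifest = manifest))
}

# md5 of the canonical JSON serialization of the config
.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
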