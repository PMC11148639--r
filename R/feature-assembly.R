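# Preprocessing of the three omic inputs and compilation into one harmonized
# feature table per timepoint parameter (BL, C2, delta = C2 - BL).

# Shift every trial's values per analyte so that baseline medians agree across
# trials. The first trial (in order of appearance) is the reference; aligning
# to its baseline median makes the procedure exactly idempotent.
.alignTrialMedians <- function(values, trial, timepoint, baseline = "BL") {
  trials <- unique(trial)
  if (length(trials) < 2L) return(values)
  isBL <- timepoint == baseline
  if (!any(isBL)) return(values)
  for (a in seq_len(nrow(values))) {
    med <- vapply(trials, function(tr) {
      v <- values[a, isBL & trial == tr]
      stats::median(v, na.rm = TRUE)
    }, numeric(1))
    target <- med[[1L]]
    if (is.na(target)) target <- stats::median(med, na.rm = TRUE)
    for (tr in trials) {
      if (is.na(med[[tr]])) next
      sel <- trial == tr
      values[a, sel] <- values[a, sel] + (target - med[[tr]])
    }
  }
  values
}

#' Preprocess serum proteomics
#'
#' Applies the serum panel rules: measurements below the analyte's limit of
#' detection are replaced by the LOD threshold; measurements carrying a
#' quality warning are replaced by the assay median (median over that
#' analyte's non-flagged measurements); finally each analyte is shifted so
#' that per-trial baseline medians agree, removing the inter-trial batch
#' effect.
#'
#' @param block an [OmicBlock-class] with \code{omic == "serum"}.
#' @param lod named numeric, limit-of-detection threshold per analyte.
#' @param warnings logical matrix (same shape as \code{block} values) flagging
#'   measurements with quality warnings; NULL for none.
#' @param baseline timepoint label treated as baseline for the median shift.
#' @return The preprocessed [OmicBlock-class].
#' @export
preprocessSerum <- function(block, lod, warnings = NULL, baseline = "BL") {
  stopifnot(is(block, "OmicBlock"))
  if (block@omic != "serum") stop("preprocessSerum expects a serum block")
  v <- block@values
  missingLod <- setdiff(rownames(v), names(lod))
  if (length(missingLod))
    stop("no LOD value for analyte(s): ", paste(missingLod, collapse = ", "))
  if (!is.null(warnings)) {
    if (!identical(dim(warnings), dim(v)))
      stop("warnings must match the value matrix in shape")
    for (a in seq_len(nrow(v))) {
      fl <- warnings[a, ]
      if (all(fl))
        stop("all measurements flagged for analyte ", rownames(v)[a],
             "; assay median undefined")
      if (any(fl))
        v[a, fl] <- stats::median(v[a, !fl], na.rm = TRUE)
    }
  }
  dn <- dimnames(v)
  v <- pmax(v, lod[rownames(v)])
  attributes(v) <- list(dim = dim(block@values), dimnames = dn)
  v <- .alignTrialMedians(v, block@trial, block@timepoint, baseline)
  initialize(block, values = v)
}

#' Preprocess bulk tumor transcriptomics
#'
#' Counts are \code{log2(count + 1)} transformed and normalized to
#' housekeeping genes by subtracting, per sample, the arithmetic mean of the
#' sample's housekeeping log2 values (geometric-mean scaling on the count
#' scale). Each gene is then shifted so per-trial baseline medians agree.
#'
#' @param block an [OmicBlock-class] of raw non-negative counts with
#'   \code{omic == "tumor_rna"}.
#' @param housekeepingGenes character, gene (row) names used as the
#'   normalization reference; all must be present.
#' @param baseline timepoint label treated as baseline for the median shift.
#' @return The normalized [OmicBlock-class] (log2 scale).
#' @export
preprocessTranscriptomics <- function(block, housekeepingGenes,
                                      baseline = "BL") {
  stopifnot(is(block, "OmicBlock"))
  if (block@omic != "tumor_rna")
    stop("preprocessTranscriptomics expects a tumor_rna block")
  v <- block@values
  if (any(v < 0, na.rm = TRUE)) stop("negative counts")
  missing <- setdiff(housekeepingGenes, rownames(v))
  if (length(missing))
    stop("housekeeping gene(s) absent: ", paste(missing, collapse = ", "))
  v <- log2(v + 1)
  hkMean <- colMeans(v[housekeepingGenes, , drop = FALSE], na.rm = TRUE)
  v <- sweep(v, 2L, hkMean, "-")
  v <- .alignTrialMedians(v, block@trial, block@timepoint, baseline)
  initialize(block, values = v)
}

#' Summarize single-cell data into per-sample cluster statistics
#'
#' Emits, per sample, (a) cluster abundance = cluster cell count / parent
#' population cell count for every cluster; and, for clusters with at least
#' \code{minCells} cells in that sample, (b) percent-positive per activation
#' marker (fraction of the cluster's cells above the marker's positivity
#' threshold) and (c) mean expression per metabolic marker. For clusters
#' below \code{minCells} only the abundance is calculated for that sample —
#' the per-marker statistics are emitted as missing — avoiding subsampling
#' error from tiny clusters.
#'
#' @param cells data.frame with columns \code{sample}, \code{cluster} and one
#'   numeric column per marker.
#' @param activationMarkers character, markers summarized as percent positive.
#' @param metabolicMarkers character, markers summarized as mean expression.
#' @param positivityThresholds named numeric, positivity threshold per
#'   activation marker (all must be present).
#' @param minCells minimum cluster size for per-marker statistics (default 15).
#' @param trial,timepoint per-sample annotations, named by sample id
#'   (recycled if length 1).
#' @param subject per-sample subject ids, named by sample id; defaults to the
#'   sample ids themselves.
#' @return An [OmicBlock-class] (\code{omic = "single_cell_summary"}) whose
#'   analytes are \code{abundance|cluster}, \code{pctpos|cluster|marker} and
#'   \code{meanexpr|cluster|marker}; percent positive is on the 0-100 scale.
#' @examples
#' mm <- matrix(c(0, 3), 2, 1, dimnames = list(NULL, "CD25"))
#' cells <- generateSingleCellFixture(c(14, 100), mm, seed = 1)
#' blk <- summarizeSingleCell(cells, activationMarkers = "CD25",
#'                            positivityThresholds = c(CD25 = 1.5))
#' @export
summarizeSingleCell <- function(cells, activationMarkers = character(),
                                metabolicMarkers = character(),
                                positivityThresholds = numeric(),
                                minCells = 15L,
                                trial = "trial1", timepoint = "BL",
                                subject = NULL) {
  stopifnot(is.data.frame(cells), all(c("sample", "cluster") %in% names(cells)))
  markers <- union(activationMarkers, metabolicMarkers)
  absent <- setdiff(markers, names(cells))
  if (length(absent))
    stop("marker column(s) absent: ", paste(absent, collapse = ", "))
  noThr <- setdiff(activationMarkers, names(positivityThresholds))
  if (length(noThr))
    stop("positivity threshold missing for: ", paste(noThr, collapse = ", "))
  if (any(is.na(cells$cluster))) stop("unlabeled cells (NA cluster)")

  samples <- unique(cells$sample)
  clusters <- sort(unique(as.character(cells$cluster)))
  cross <- function(prefix, mks) {
    if (!length(mks)) return(character(0))
    as.vector(t(outer(clusters, mks,
                      function(cl, mk) paste0(prefix, "|", cl, "|", mk))))
  }
  feats <- c(paste0("abundance|", clusters),
             cross("pctpos", activationMarkers),
             cross("meanexpr", metabolicMarkers))
  out <- matrix(NA_real_, nrow = length(feats), ncol = length(samples),
                dimnames = list(feats, samples))
  for (s in samples) {
    sub <- cells[cells$sample == s, , drop = FALSE]
    parentN <- nrow(sub)
    for (cl in clusters) {
      inCl <- sub[as.character(sub$cluster) == cl, , drop = FALSE]
      n <- nrow(inCl)
      out[paste0("abundance|", cl), s] <- n / parentN
      if (n >= minCells) {
        for (mk in activationMarkers)
          out[paste0("pctpos|", cl, "|", mk), s] <-
            100 * mean(inCl[[mk]] > positivityThresholds[[mk]])
        for (mk in metabolicMarkers)
          out[paste0("meanexpr|", cl, "|", mk), s] <- mean(inCl[[mk]])
      }
    }
  }
  stat <- sub("\\|.*$", "", feats)
  stat[stat == "abundance"] <- "abundance"
  stat[stat == "pctpos"] <- "pct_positive"
  stat[stat == "meanexpr"] <- "mean_expression"
  if (is.null(subject)) subject <- stats::setNames(samples, samples)
  ad <- DataFrame(analyte = feats, statistic = stat,
                  cluster = sub("^[^|]*\\|([^|]*).*$", "\\1", feats))
  OmicBlock(out, omic = "single_cell_summary",
            subject = unname(subject[samples]),
            trial = if (length(trial) == 1L) trial else unname(trial[samples]),
            timepoint = if (length(timepoint) == 1L) timepoint
                        else unname(timepoint[samples]),
            analyteData = ad)
}

#' Assemble omic blocks into one feature table
#'
#' Compiles all blocks' analytes into a single subjects-by-features table for
#' the requested timepoint parameter. For \code{"delta"}, each feature is
#' value(C2) minus value(BL), computed before any imputation so that imputed
#' endpoint values never fabricate a change; a delta is missing when either
#' endpoint is. Remaining missing entries are then replaced by the column
#' (feature) mean over subjects, and every imputed cell is recorded in the
#' \code{imputed} assay mask. Zero-variance features are retained but flagged
#' in \code{rowData()$constant}.
#'
#' @param blocks list of [OmicBlock-class] objects sharing a subject universe.
#' @param timepointParam "BL", "C2" or "delta".
#' @param timepoints for \code{"delta"}, the (baseline, later) pair of
#'   timepoint labels.
#' @return An [ImmuneFeatureTable-class] with assays \code{values} (fully
#'   imputed) and \code{imputed} (logical mask).
#' @export
assembleFeatures <- function(blocks, timepointParam = c("BL", "C2", "delta"),
                             timepoints = c("BL", "C2")) {
  timepointParam <- match.arg(timepointParam)
  stopifnot(length(blocks) >= 1L)
  getMat <- function(block, tp) {
    sel <- block@timepoint == tp
    m <- block@values[, sel, drop = FALSE]
    colnames(m) <- block@subject[sel]
    rownames(m) <- paste(block@omic, rownames(block@values), sep = ":")
    m
  }
  pieces <- lapply(blocks, function(b) {
    if (timepointParam == "delta") {
      bl <- getMat(b, timepoints[1L]); c2 <- getMat(b, timepoints[2L])
      common <- intersect(colnames(bl), colnames(c2))
      c2[, common, drop = FALSE] - bl[, common, drop = FALSE]
    } else {
      getMat(b, timepointParam)
    }
  })
  subjects <- sort(unique(unlist(lapply(pieces, colnames))))
  if (!length(subjects)) stop("no samples at the requested timepoint(s)")
  mat <- do.call(rbind, lapply(pieces, function(m) {
    full <- matrix(NA_real_, nrow = nrow(m), ncol = length(subjects),
                   dimnames = list(rownames(m), subjects))
    full[, colnames(m)] <- m
    full
  }))

  allNA <- rowSums(!is.na(mat)) == 0L
  if (any(allNA))
    stop("feature(s) missing for all subjects: ",
         paste(utils::head(rownames(mat)[allNA], 5L), collapse = ", "))
  mask <- is.na(mat)
  if (any(mask)) {
    rm <- rowMeans(mat, na.rm = TRUE)
    idx <- which(mask, arr.ind = TRUE)
    mat[idx] <- rm[idx[, 1L]]
  }
  constant <- apply(mat, 1L, function(x) stats::sd(x) == 0)

  omic <- rep(vapply(blocks, function(b) b@omic, character(1)),
              vapply(pieces, nrow, integer(1)))
  stat <- unlist(lapply(seq_along(blocks), function(i) {
    ad <- blocks[[i]]@analyteData
    s <- if ("statistic" %in% names(ad)) ad$statistic
         else if (blocks[[i]]@omic == "tumor_rna") "expression"
         else "abundance"
    kept <- sub("^[^:]*:", "", rownames(pieces[[i]]))
    rep_len(s, nrow(blocks[[i]]@values))[match(kept, rownames(blocks[[i]]@values))]
  }))
  new("ImmuneFeatureTable", SummarizedExperiment(
    assays = list(values = mat, imputed = mask),
    rowData = DataFrame(omic = omic,
                        analyte = sub("^[^:]*:", "", rownames(mat)),
                        statistic = stat, constant = unname(constant),
                        row.names = rownames(mat)),
    colData = DataFrame(subject = subjects, row.names = subjects),
    metadata = list(timepointParam = timepointParam)))
}

#' Build an ImmuneFeatureTable directly from a matrix
#'
#' Lightweight constructor for tables already on the feature scale (e.g.
#' loaded from disk or simulated); applies column-mean imputation and the
#' imputation mask exactly as [assembleFeatures()] does.
#'
#' @param values features x subjects numeric matrix (may contain NA).
#' @param timepointParam "BL", "C2" or "delta".
#' @param colData optional per-subject [S4Vectors::DataFrame].
#' @param impute replace missing values by the feature mean (default TRUE).
#' @return An [ImmuneFeatureTable-class].
#' @export
ImmuneFeatureTable <- function(values, timepointParam = "BL", colData = NULL,
                               impute = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feature", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  assays <- list(values = values)
  if (impute) {
    allNA <- rowSums(!is.na(values)) == 0L
    if (any(allNA)) stop("feature(s) missing for all subjects")
    mask <- is.na(values)
    if (any(mask)) {
      rm <- rowMeans(values, na.rm = TRUE)
      idx <- which(mask, arr.ind = TRUE)
      values[idx] <- rm[idx[, 1L]]
    }
    assays <- list(values = values, imputed = mask)
  }
  if (is.null(colData))
    colData <- DataFrame(subject = colnames(values),
                         row.names = colnames(values))
  constant <- apply(values, 1L, function(x) stats::sd(x) == 0)
  new("ImmuneFeatureTable", SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(omic = "serum", analyte = rownames(values),
                        statistic = "expression", constant = unname(constant),
                        row.names = rownames(values)),
    colData = colData,
    metadata = list(timepointParam = timepointParam)))
}

#' Column-mean imputation of an ImmuneFeatureTable
#'
#' Replaces every missing value with its feature's mean over subjects and
#' records the mask; a no-op (empty mask) on complete tables.
#'
#' @param x an [ImmuneFeatureTable-class].
#' @return The imputed table with assays \code{values} and \code{imputed}.
#' @export
imputeColumnMean <- function(x) {
  stopifnot(is(x, "ImmuneFeatureTable"))
  v <- assay(x, "values")
  allNA <- rowSums(!is.na(v)) == 0L
  if (any(allNA)) stop("feature(s) missing for all subjects")
  mask <- is.na(v)
  if (any(mask)) {
    rm <- rowMeans(v, na.rm = TRUE)
    idx <- which(mask, arr.ind = TRUE)
    v[idx] <- rm[idx[, 1L]]
  }
  out <- SummarizedExperiment(
    assays = list(values = v, imputed = mask),
    rowData = rowData(x), colData = colData(x),
    metadata = metadata(x))
  new("ImmuneFeatureTable", out)
}
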