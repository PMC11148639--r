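# TCR repertoire metrics: neoplastic clone identification, Gini-Simpson
# diversity, Morisita-Horn similarity, differential clone abundance, and the
# clones-of-interest compilation.

#' Identify the neoplastic clone of a repertoire
#'
#' The neoplastic clone is the single most abundant clonal family provided it
#' carries at least \code{minCount} templates (default 75); otherwise no
#' clone is called. A tie for most-abundant at or above the cutoff is an
#' error: the neoplastic identity must be unambiguous.
#'
#' @param rep a [Repertoire-class].
#' @param minCount minimum template count for the call (default 75).
#' @return clone key (\code{"V|J|CDR3"}) or \code{NULL} when no clone
#'   qualifies.
#' @examples
#' r <- Repertoire(data.frame(v_gene = c("TRBV9", "TRBV5"),
#'                            j_gene = "TRBJ1-1",
#'                            cdr3_aa = c("CASSA", "CASSB"),
#'                            templates = c(100, 5)))
#' identifyNeoplastic(r)
#' @export
identifyNeoplastic <- function(rep, minCount = 75L) {
  stopifnot(is(rep, "Repertoire"))
  counts <- rep@clones$templates
  if (!length(counts)) stop("empty repertoire")
  mx <- max(counts)
  if (mx < minCount) return(NULL)
  top <- which(counts == mx)
  if (length(top) > 1L)
    stop("ambiguous neoplastic clone: tie for most abundant at ", mx,
         " templates")
  cloneKeys(rep@clones)[top]
}

#' Gini-Simpson diversity of a repertoire
#'
#' \eqn{D = 1 - \sum_i p_i^2} over clone frequencies, optionally after
#' excluding given clones (e.g. the neoplastic clonotype) and renormalizing
#' the remaining frequencies.
#'
#' @param rep a [Repertoire-class].
#' @param exclude optional character vector of clone keys to drop before
#'   renormalization.
#' @return diversity in \eqn{[0, 1 - 1/n]}.
#' @examples
#' r <- Repertoire(data.frame(v_gene = c("TRBV9", "TRBV5"),
#'                            j_gene = "TRBJ1-1",
#'                            cdr3_aa = c("CASSA", "CASSB"),
#'                            templates = c(3, 1)))
#' giniSimpson(r)  # 1 - (9/16 + 1/16) = 0.375
#' @export
giniSimpson <- function(rep, exclude = NULL) {
  stopifnot(is(rep, "Repertoire"))
  keys <- cloneKeys(rep@clones)
  keep <- !(keys %in% exclude)
  counts <- rep@clones$templates[keep]
  if (!length(counts)) stop("exclusion removes all clones")
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Morisita-Horn similarity between two repertoires
#'
#' \eqn{MH = 2 \sum_i x_i y_i / ((d_x + d_y) X Y)} over the clone union,
#' where \eqn{X, Y} are total template counts and
#' \eqn{d_x = \sum_i x_i^2 / X^2}. Equals 1 for proportionally identical
#' repertoires and 0 for disjoint clone sets; invariant to proportional
#' scaling of either repertoire's counts.
#'
#' @param repA,repB [Repertoire-class] objects.
#' @return similarity in [0, 1].
#' @export
morisitaHorn <- function(repA, repB) {
  stopifnot(is(repA, "Repertoire"), is(repB, "Repertoire"))
  kA <- cloneKeys(repA@clones); kB <- cloneKeys(repB@clones)
  union <- union(kA, kB)
  x <- stats::setNames(numeric(length(union)), union)
  y <- x
  x[kA] <- repA@clones$templates
  y[kB] <- repB@clones$templates
  X <- sum(x); Y <- sum(y)
  if (X == 0 || Y == 0) stop("empty repertoire")
  dx <- sum(x^2) / X^2
  dy <- sum(y^2) / Y^2
  2 * sum(x * y) / ((dx + dy) * X * Y)
}

#' Differentially abundant clones between two repertoires
#'
#' Per clone in the union, builds the 2x2 table of (clone templates vs
#' remaining templates) in each repertoire, applies the two-sided Fisher's
#' exact test, and corrects across all union clones by Benjamini-Hochberg.
#'
#' @param repA,repB [Repertoire-class] objects.
#' @param qCut FDR cutoff for the \code{significant} flag; the study uses
#'   0.05 for clones-of-interest and 0.1 elsewhere.
#' @return A [S4Vectors::DataFrame] with per-clone counts, \code{p},
#'   \code{q}, \code{significant}, ordered by q.
#' @export
differentialClones <- function(repA, repB, qCut = 0.05) {
  stopifnot(is(repA, "Repertoire"), is(repB, "Repertoire"))
  X <- totalTemplates(repA); Y <- totalTemplates(repB)
  if (X == 0 || Y == 0) stop("zero total templates")
  kA <- cloneKeys(repA@clones); kB <- cloneKeys(repB@clones)
  union <- union(kA, kB)
  xa <- stats::setNames(numeric(length(union)), union)
  xb <- xa
  xa[kA] <- repA@clones$templates
  xb[kB] <- repB@clones$templates
  p <- vapply(union, function(k) {
    tb <- matrix(c(xa[[k]], X - xa[[k]], xb[[k]], Y - xb[[k]]), nrow = 2L)
    stats::fisher.test(tb)$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  out <- DataFrame(clone = union, countA = unname(xa), countB = unname(xb),
                   freqA = unname(xa) / X, freqB = unname(xb) / Y,
                   p = unname(p), q = unname(q), significant = unname(q) < qCut)
  out[order(out$q, out$p), ]
}

#' Compile clones of interest across samples
#'
#' The union of four criteria, each tagged per clone: (a) neoplastic clones
#' (per-sample most-abundant clone with at least \code{minCount} templates);
#' (b) tumor-present clones (observed in any tumor repertoire); (c) abundant
#' clones, exceeding \code{abundanceCut} of a sample's TCR templates
#' (default 0.01\%, evaluated per sample); and (d) clones significantly
#' differentially abundant between any two of the blood repertoires
#' (BH-corrected Fisher's exact test at \code{qCut}).
#'
#' @param repertoires named list of blood [Repertoire-class] objects (e.g.
#'   one per timepoint).
#' @param tumorRepertoires optional list of tumor [Repertoire-class] objects.
#' @param abundanceCut per-sample frequency cutoff (default 1e-4, i.e. 0.01\%).
#' @param qCut FDR cutoff for the differential criterion (default 0.05).
#' @param minCount neoplastic-clone template cutoff (default 75).
#' @return A [S4Vectors::DataFrame] with one row per clone of interest and
#'   logical columns \code{neoplastic}, \code{tumorPresent},
#'   \code{abundant}, \code{differential}.
#' @export
clonesOfInterest <- function(repertoires, tumorRepertoires = list(),
                             abundanceCut = 1e-4, qCut = 0.05,
                             minCount = 75L) {
  stopifnot(length(repertoires) >= 1L)
  neo <- unique(unlist(lapply(repertoires, function(r) {
    n <- tryCatch(identifyNeoplastic(r, minCount = minCount), error = function(e) NULL)
    n %||% character(0)
  })))
  tumor <- unique(unlist(lapply(tumorRepertoires,
                                function(r) cloneKeys(r@clones))))
  abundant <- unique(unlist(lapply(repertoires, function(r) {
    f <- cloneFrequencies(r)
    names(f)[f > abundanceCut]
  })))
  differential <- character(0)
  if (length(repertoires) >= 2L) {
    pairs <- utils::combn(length(repertoires), 2L)
    for (j in seq_len(ncol(pairs))) {
      dc <- differentialClones(repertoires[[pairs[1L, j]]],
                               repertoires[[pairs[2L, j]]], qCut = qCut)
      differential <- union(differential, dc$clone[dc$significant])
    }
  }
  clones <- unique(c(neo, tumor, abundant, differential))
  DataFrame(clone = clones,
            neoplastic = clones %in% neo,
            tumorPresent = clones %in% tumor,
            abundant = clones %in% abundant,
            differential = clones %in% differential)
}

#' Read a clone count table
#'
#' Reads a delimited text file with columns \code{v_gene}, \code{j_gene},
#' \code{cdr3_aa}, \code{templates} into a [Repertoire-class], collapsing
#' duplicate clonal families by summing their template counts.
#'
#' @param path file path (tab-delimited by default).
#' @param sample sample identifier (default: file base name).
#' @param sep field separator.
#' @return A [Repertoire-class].
#' @export
readRepertoire <- function(path, sample = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("v_gene", "j_gene", "cdr3_aa", "templates")
  if (!all(need %in% names(df)))
    stop("clone table needs columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(templates ~ v_gene + j_gene + cdr3_aa, df, sum)
  Repertoire(agg, sample = sample %||% sub("\\.[^.]*$", "", basename(path)))
}
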