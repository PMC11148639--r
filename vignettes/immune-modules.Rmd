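---
title: "Immune modules: methods and design notes"
author: "immunoModules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune modules: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoModules)
```

# The problem

Cutaneous T cell lymphoma (CTCL) cohorts profiled under immunotherapy produce
three heterogeneous data streams per patient and timepoint: serum proteomics
panel values, bulk tumor transcriptomics, and per-sample single-cell
(mass-cytometry) event tables summarized per cluster. Individually these
features are noisy and massively collinear; the question — which coordinated
immune programs separate responders (R) from non-responders (NR), or mycosis
fungoides (MF) from Sezary syndrome (SS) — is better posed at the level of
*immune modules*: groups of features that co-vary across subjects, summarized
by one score per module per subject.

This package implements that framework end to end: feature assembly, module
discovery, module summarization, random-forest stratification with a
seed-stability procedure, the companion differential statistics, TCR
repertoire metrics, and a synthetic cohort generator that makes every stage
testable with known ground truth.

# Feature assembly

Each omic block is preprocessed with the platform's conventions:

* **Serum proteomics** — values below an analyte's limit of detection (LOD)
  are replaced with the LOD threshold; measurements carrying quality warnings
  are replaced by the assay median over non-flagged measurements; each analyte
  is then shifted so that per-trial *baseline* medians agree, removing the
  inter-trial batch effect. The shift aligns every trial to the first trial's
  baseline median. That reference-trial formulation is exactly idempotent —
  re-aligning an aligned block is a no-op — which a pooled-median target is
  not.
* **Bulk transcriptomics** — counts are `log2(count + 1)` transformed and
  normalized to designated housekeeping genes by subtracting, per sample, the
  arithmetic mean of the sample's housekeeping log2 values (geometric-mean
  scaling on the count scale, the standard convention for targeted expression
  panels). The `+ 1` pseudocount avoids `log(0)`; both the pseudocount and
  the normalization are stated choices, since only "log2, normalized to
  housekeeping genes" is fixed by the method itself. The inter-trial baseline
  median shift is then applied per gene.
* **Single-cell summaries** — per sample and cluster: abundance (cluster
  cells / parent cells), percent positive per activation marker (fraction of
  cells above a configured positivity threshold, 0–100 scale), and mean
  expression per metabolic marker. A cluster with fewer than 15 cells in a
  sample contributes *only* its abundance; the per-marker statistics are
  emitted as missing, never computed from fewer than 15 cells, avoiding
  subsampling error. Positivity thresholds are configuration inputs because
  gates are derived manually upstream; the parent population for abundances
  is likewise configurable (e.g. out of all cells vs out of non-neoplastic
  T cells).

`assembleFeatures()` compiles the blocks into one features-by-subjects table
per timepoint parameter — BL, C2, or delta = C2 − BL. Deltas are computed
**before** imputation, so an imputed endpoint can never fabricate a change;
a delta is missing whenever either endpoint is. Remaining missing entries are
replaced by the feature mean over subjects (which preserves each feature's
mean exactly) and every imputed cell is recorded in a logical mask, so the
minimum-cell rule and the imputation are fully auditable downstream.

# Module discovery

For one timepoint parameter, pairwise Spearman correlation $\rho_{ij}$ is
computed across all subjects (average ranks under ties; zero-variance
features are assigned correlation 0 against everything and flagged). The
correlation matrix is mapped to a dissimilarity

$$d_{ij} = 1 - \rho_{ij}^4 .$$

Raising $\rho$ to the fourth power removes the sign — strongly anticorrelated
features co-cluster, deliberately — and pushes moderately correlated pairs
toward distance 1, sharpening block structure.

Features are clustered by the Ward method applied directly to this
dissimilarity (the Lance–Williams Ward update on the given distances, i.e.
"Ward on dissimilarities" — `hclust(method = "ward.D")` — not Ward in an
embedded Euclidean space; the agglomeration method is an argument). The tree
is cut at every candidate module count $k$ in `2:min(p - 1, 100)` by default,
a range that spans under- to over-clustering without quadratic cost; the mean
silhouette width, computed against the same distance matrix with singleton
clusters contributing width 0 (the standard convention; the criterion stays
defined at every cut), is recorded per $k$, and the silhouette-maximal $k$ is
selected with ties broken toward smaller $k$ (parsimony, determinism).

Each module is summarized per subject by the first principal component of its
Z-scored member features. Constant features Z-score to all zeros; a module
containing only constant features is an error. The PC1 sign is oriented so
the score correlates non-negatively with the mean member Z-score, which makes
scores reproducible across platforms (eigenvectors are otherwise defined only
up to sign). For an equicorrelated module of $m$ features at correlation
$\rho$ the PC1 variance explained approaches $(1 + (m - 1)\rho)/m$ — about
0.83 for $m = 6$, $\rho = 0.8$ — which is the quantitative check used in the
tests.

# Classifier stage

Module scores feed a random-forest classifier (`ranger`). Hyperparameters are
selected by minimizing out-of-bag (OOB) error over a small grid —
`mtry` $\in \lceil\sqrt{p}\cdot\{0.5, 1, 2\}\rceil$, minimum node size
$\{1, 3, 5\}$, 1000 trees — under a fixed tuning seed, ties broken toward
smaller `mtry` then smaller node size. The grid is a stated choice: the
procedure fixes only "minimize OOB error".

The tuned model is rerun across ten seeds. Per seed, features are ranked by
Gini importance; each seed's top ten receive weight $11 - \mathrm{rank}$, and
weights are summed across seeds into a consensus score. The representative
seed is the one whose top-ten list carries the largest total consensus score
(ties toward the lowest seed value); its Gini vector is used downstream. The
linear rank weight and the overlap score are the simplest schemes consistent
with "weighted by rank, summed" and "most overlapping", and both are
configurable in principle; the defaults are what the package tests. Modules
with Gini strictly above a per-model threshold are selected; with
`threshold = "auto"` the cutoff is the midpoint of the largest gap in the
decreasing Gini sequence, and the numeric cutoff actually used is always
reported. Class imbalance beyond 2:1 triggers a warning but no reweighting.

`compareTimepoints()` runs modules + tuning independently per timepoint
parameter and flags the minimum OOB error as the analysis focus.

# Companion statistics

* **Differential distributions** — Wilcoxon rank-sum (unpaired) or signed-rank
  (paired); exact p-values for small tie-free samples, tie-corrected normal
  approximation otherwise; Benjamini–Hochberg q-values over the tested set.
  The effect size is Cohen's d (pooled-SD standardized mean difference), or
  mean paired difference over the SD of differences. An |ES| > 1 significance
  clause is only coherent for an unbounded standardized-difference measure,
  which is why Cohen's d is the default. A feature is significant when
  `q < 0.1` **or** (`p < 0.05` and `|ES| > 1`). Tests are two-sided
  throughout. Constant features report p = 1, ES = 0, flagged.
* **Count data** — two-sided Fisher's exact test per 2×2 unit, BH across
  units.
* **Z stratification** — selected features are column-Z-scored; subjects are
  Ward-clustered on Euclidean distances between Z rows; per-group mean Z per
  feature is reported, and a between-timepoint change in mean Z exceeding 0.5
  in absolute value is flagged substantial.
* **Mahalanobis attribution** — per feature, the univariate Mahalanobis
  distance of one outlying subject to each of two group distributions
  ($d_G = |x - \bar x_G| / s_G$, outlier excluded); features with
  $\Delta = d_A - d_B > 0.3$ are attributed (the outlier resembles group B).
  The per-feature univariate form is the only tractable one here — features
  far outnumber subjects, so a pooled covariance would be singular — and is
  also what a per-feature attribution display requires. Zero-SD features are
  skipped and flagged. Swapping the groups negates $\Delta$.

# TCR repertoire metrics

Clonal families are identified by V gene + J gene + CDR3. The neoplastic
clone of a sample is the single most abundant clone if it has at least 75
templates; a tie at the maximum is an error rather than an arbitrary pick,
because neoplastic identity must be unambiguous. Gini–Simpson diversity
($1 - \sum p_i^2$, optionally excluding given clones and renormalizing) and
Morisita–Horn similarity (abundance-weighted overlap over the clone union)
are computed in closed form; differential clone abundance uses per-clone
2×2 Fisher tests (clone vs remaining templates per sample) with BH
correction. Clones of interest union four tagged criteria: neoplastic,
tumor-present, abundant (> 0.01% of a sample's templates — evaluated per
sample, the permissive reading of an ambiguous rule, and configurable), and
differentially abundant (q < 0.05 by default; 0.1 is the other cutoff in
use).

# The synthetic cohort generator

The generator defines the package's study conditions. Features follow a
single-latent-factor model per module: member $= \sqrt{\rho}\,f +
\sqrt{1-\rho}\,\varepsilon$ with all terms standard normal, so expected
within-module pairwise correlation is exactly $\rho$ and between-module
correlation is 0. Generation is on the Gaussian scale; Spearman and Pearson
correlations agree there up to a known monotone map, well within the
tolerances used. Discriminative modules shift the latent factor mean by the
stated standardized amount between the two groups. Missingness is injected
completely at random — the imputation being emulated (column mean) assumes no
particular mechanism, and no mechanism is specified upstream, so MCAR is an
assumption, not inferred intent. LOD censoring replaces each feature's lower
`lodRate` tail with the threshold value. Repertoires draw Zipf-skewed clone
counts (every clone gets at least one template); a planted neoplastic clone
receives exactly its requested count and the remaining clones are capped
below it, so the planted clone is guaranteed to be the unique most abundant —
the contract the ≥ 75-template rule needs. One integer seed drives all
sub-generators through derived streams, and the session RNG is left
untouched.

Default conditions (40 subjects as 20 vs 20, 8 modules × 6 features at
$\rho = 0.8$, 12 noise features, one discriminative module at 1.5σ, 2%
missingness, 5% LOD censoring) are the regime all simulation checks run at.

What the generator does *not* emulate: non-Gaussian marginals, informative
missingness, batch effects beyond a median shift, correlated noise between
modules, cluster-size variation tied to clinical state, or sequencing error
in clone calls. Passing tests therefore demonstrate correctness of the
procedures under a clean, favorable data-generating process — not robustness
to everything real cohorts do.

# Numerical choices and degenerate inputs

* Correlations are clipped to [−1, 1] before the distance transform; the
  diagonal is forced to 0.
* Constant features: correlation 0 everywhere, Z-score 0, flagged; they
  cluster like any feature but cannot carry a module alone.
* Silhouette of singleton clusters is 0; an all-zero distance matrix is an
  error (no structure to cluster).
* PC1 orientation: sign flipped when the score's covariance with the mean
  member Z-score is negative; exact zero covariance keeps the positive sign.
* All forests run single-threaded with explicit seeds; rankings, consensus
  scores and seed selections are bit-reproducible.
* Exact Wilcoxon p-values require tie-free samples (the implementation falls
  back to the tie-corrected normal approximation, as `wilcox.test` does).

# Problem sizes used by the checks

The simulation-based checks run 20 replicates per claim at the default cohort
size (40 subjects, 60 features), with 10 stability seeds and a 9-point tuning
grid per replicate; the all-null false-discovery check uses 500 features × 20
subjects × 20 replicates. The end-to-end determinism check runs the full
pipeline twice on a 3-module, 20-subject configuration. These sizes were
chosen so the whole suite exercises every stage at the study conditions while
remaining comfortable to run interactively.

# Known limitations

* With unstructured noise features present, the silhouette-selected module
  count exceeds the planted count: noise features form one or more diffuse
  clusters of their own (their mutual distances are ~1, the same as their
  distance to everything), and the mean-silhouette curve is nearly flat
  across the corresponding range of k. The planted modules themselves are
  still recovered essentially perfectly (adjusted Rand index ≈ 1 on module
  features); only the count of extra noise clusters is unstable. Without
  noise features, the selected k equals the planted module count.
* OOB error at 40 subjects carries binomial noise of roughly ±0.08, and the
  min-over-grid tuning rule adds a small winner's-curse downward bias; OOB
  point values at this cohort size should be read with that spread in mind.
* The Gini "auto" threshold (largest gap) is a heuristic; for models whose
  importance sequence decays smoothly it can be unstable, which is why the
  numeric cutoff used is always reported alongside the selection.
* Excluding a dominant clone raises Gini–Simpson diversity only when the
  residual repertoire is sufficiently polyclonal (residual concentration
  $\sum q_i^2 \le p_{dom}/(2 - p_{dom})$); for a residual dominated by a
  second large clone, exclusion can lower diversity.

# A compact worked example

```{r example, eval = FALSE}
spec <- CohortSpec(20, nModules = 8, featuresPerModule = 6,
                   withinModuleRho = 0.8, nNoiseFeatures = 12,
                   discriminativeModules = c("1" = 1.5), seed = 1)
cohort <- generateFeatureCohort(spec)
tab <- imputeColumnMean(cohort$table)
mod <- discoverModules(tab)
cfg <- tuneForest(mod$scores, cohort$truth@groupLabel)
res <- stabilitySelect(cfg, mod$scores, cohort$truth@groupLabel, seeds = 1:10)
res
```

The full pipeline — simulation through TCR metrics, with TSV outputs and a
reproducibility manifest — is `runPipeline()`; see the README for a run with
its printed output.
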