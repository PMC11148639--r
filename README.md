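# immunoModules

Multi-omic **immune module** discovery and patient stratification for
immunotherapy cohorts, with the companion differential statistics and T cell
receptor (TCR) repertoire metrics.

## The problem and who this is for

Trials in cutaneous T cell lymphoma (CTCL) — and immunotherapy trials
generally — profile each patient with serum proteomics, bulk tumor
transcriptomics, and mass-cytometry (summarized per cell cluster), at several
timepoints (baseline BL, treatment cycles C2, ...). The features are noisy
and strongly collinear, and the scientific question ("which coordinated
immune programs separate responders from non-responders?") lives at the
level of *modules* of co-varying features, not individual analytes. This
package is for computational biologists who want that analysis as a tested,
reproducible pipeline, and who need to validate every stage on synthetic
cohorts with known ground truth.

## The method

1. **Feature assembly.** Platform preprocessing (limit-of-detection
   replacement, assay-median replacement of flagged values, log2 +
   housekeeping normalization, inter-trial baseline median alignment,
   per-cluster single-cell summaries with a minimum-15-cell rule), then
   compilation into one subjects × features table per timepoint parameter
   (BL, C2, Δ = C2 − BL; Δ computed before imputation). Missing entries are
   replaced by the column mean, with a full imputation mask.
2. **Module discovery.** Spearman correlation ρ across subjects; distance
   *d* = 1 − ρ⁴ (sign-blind, sharpens block structure); Ward clustering on
   the precomputed dissimilarity; the module count k maximizes the mean
   silhouette width; each module is summarized per subject by PC1 of its
   Z-scored members (sign-oriented, variance explained reported).
3. **Stratification.** A random forest on module scores, tuned by
   out-of-bag (OOB) error, rerun over ten seeds; per-seed top-ten Gini
   features are rank-weighted (11 − rank) and summed into a consensus; the
   representative seed maximizes consensus overlap; modules with Gini above
   a threshold (explicit or largest-gap "auto") are selected. Timepoint
   parameters are compared by tuned OOB error.
4. **Companion statistics.** Wilcoxon rank-sum / signed-rank and Fisher
   exact tests with Benjamini–Hochberg correction and the combined rule
   *q* < 0.1 or (*p* < 0.05 and |ES| > 1, ES = Cohen's d); Z-score
   stratification with Ward clustering of subjects; per-feature Mahalanobis
   attribution of an outlier subject (Δ distance > 0.3).
5. **TCR metrics.** Neoplastic clone = most abundant clone with ≥ 75
   templates; Gini-Simpson diversity (with optional clone exclusion);
   Morisita-Horn similarity; differential clone abundance (Fisher + BH);
   clones-of-interest compilation (neoplastic / tumor-present / > 0.01%
   abundant / differential).
6. **Synthetic cohorts.** A latent-factor generator
   (feature = √ρ·factor + √(1−ρ)·noise) with planted modules, planted group
   shifts, MCAR missingness, LOD censoring, and skewed repertoires with a
   planted dominant clone — the ground truth every stage is tested against.

## A worked example

```r
library(immunoModules)

spec <- CohortSpec(20, nModules = 8, featuresPerModule = 6,
                   withinModuleRho = 0.8, nNoiseFeatures = 12,
                   discriminativeModules = c("1" = 1.5), seed = 1)
cohort <- generateFeatureCohort(spec)
tab <- imputeColumnMean(cohort$table)

mod <- discoverModules(tab)
mod$assignment
#> ModuleAssignment: 60 features in 10 modules (silhouette-selected)
#>   module sizes: 6, 6, 6, 6, 6, 6, 6, 6, 10, 2
#>   mean silhouette at k = 10 : 0.335
mod$scores
#> ModuleScores: 40 subjects x 10 modules (PC1 summaries)
#>   variance explained: 0.92, 0.84, 0.86, 0.87, 0.88, 0.82, 0.82, 0.8, 0.19, 0.72

cfg <- tuneForest(mod$scores, cohort$truth@groupLabel)
cfg
#> TunedConfig: mtry = 2 , min node size = 1 , trees = 1000
#>   OOB error: 0.25 (grid of 9 points)

res <- stabilitySelect(cfg, mod$scores, cohort$truth@groupLabel, seeds = 1:10)
res
#> ClassifierResult: 10 seeds, representative seed 1
#>   per-seed OOB error: 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.275, 0.25, 0.25, 0.25
#>   Gini threshold: 3.625 -> 1 selected: module1
head(consensusRanking(res))
#>  module1  module6  module5  module2  module3 module10
#>      100       86       84       69       53       52
```

Reading this: the 8 planted 6-feature modules are recovered exactly (the two
extra clusters absorb the 12 unstructured noise features); PC1 explains
~0.8–0.9 of the variance inside real modules and only 0.19 of the noise
cluster; the planted discriminative module (`module1`) has the maximal
consensus weight (100 = 10 seeds × weight 10) and is the single module above
the auto Gini threshold.

The full pipeline — simulation through TCR metrics, with TSV outputs per
stage and a JSON reproducibility manifest — is one call:

```r
runPipeline(list(), outDir = "run1", seed = 1)
```

A thin command-line wrapper is included at
`inst/scripts/immunomodules.R` (`run` and `simulate` subcommands).

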