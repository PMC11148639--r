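serumBlock <- function(values, trial = "trial1", timepoint = "BL",
                       subjects = NULL) {
  values <- as.matrix(values)
  if (is.null(subjects)) subjects <- paste0("P", seq_len(ncol(values)))
  OmicBlock(values, omic = "serum", subject = subjects, trial = trial,
            timepoint = timepoint)
}

test_that("serum preprocessing applies LOD, warning-median and trial-shift rules", {
  v <- matrix(c(2.0, 4.0, 5.0, 6.0), nrow = 1,
              dimnames = list("IL6", NULL))
  blk <- serumBlock(v)
  out <- preprocessSerum(blk, lod = c(IL6 = 3.1))
  expect_equal(unname(out@values[1, 1]), 3.1)  # below-LOD -> LOD threshold
  expect_equal(out@values[1, -1], v[1, -1])

  # flagged value replaced by the median of non-flagged measurements
  v2 <- matrix(c(1, 2, 3, 99), nrow = 1, dimnames = list("IL8", NULL))
  warn <- matrix(c(FALSE, FALSE, FALSE, TRUE), nrow = 1)
  out2 <- preprocessSerum(serumBlock(v2), lod = c(IL8 = 0), warnings = warn)
  expect_equal(unname(out2@values[1, 4]), 2)
  allFlag <- matrix(TRUE, 1, 4)
  expect_error(preprocessSerum(serumBlock(v2), lod = c(IL8 = 0),
                               warnings = allFlag), "median undefined")

  # trial medians aligned at baseline: A median 4, B median 5 -> B shifted -1
  v3 <- matrix(c(3, 4, 5, 4, 5, 6), nrow = 1, dimnames = list("IL2", NULL))
  blk3 <- serumBlock(v3, trial = rep(c("A", "B"), each = 3))
  out3 <- preprocessSerum(blk3, lod = c(IL2 = 0))
  expect_equal(unname(out3@values[1, 4:6]), c(3, 4, 5))
  medA <- median(out3@values[1, 1:3]); medB <- median(out3@values[1, 4:6])
  expect_equal(medA, medB)
})

test_that("trial median alignment is idempotent", {
  set.seed(42)
  v <- matrix(rnorm(60, mean = rep(c(0, 2), each = 30)), nrow = 3)
  rownames(v) <- paste0("an", 1:3)
  blk <- serumBlock(v, trial = rep(c("A", "B"), each = 10),
                    timepoint = rep(c("BL", "C2"), times = 10))
  lod <- setNames(rep(-Inf, 3), rownames(v))
  lod[] <- -100
  once <- preprocessSerum(blk, lod = lod)
  twice <- preprocessSerum(once, lod = lod)
  expect_equal(twice@values, once@values, tolerance = 1e-12)
})

test_that("transcriptomics normalization subtracts housekeeping log2 means", {
  # housekeeping log2 values {5, 7} -> mean 6; gene log2 value 10 -> 4
  counts <- matrix(c(2^5 - 1, 2^7 - 1, 2^10 - 1), ncol = 1,
                   dimnames = list(c("hk1", "hk2", "geneA"), "P1"))
  blk <- OmicBlock(counts, omic = "tumor_rna", subject = "P1")
  out <- preprocessTranscriptomics(blk, housekeepingGenes = c("hk1", "hk2"))
  expect_equal(out@values["geneA", 1], 4)
  expect_equal(out@values["hk1", 1], -1)       # 5 - 6

  # all genes at the housekeeping mean -> all zeros
  flat <- matrix(2^3 - 1, nrow = 3, ncol = 2,
                 dimnames = list(c("hk1", "hk2", "g"), NULL))
  out2 <- preprocessTranscriptomics(
    OmicBlock(flat, omic = "tumor_rna", subject = c("P1", "P2")), c("hk1", "hk2"))
  expect_true(all(out2@values == 0))

  expect_error(preprocessTranscriptomics(
    OmicBlock(flat, omic = "tumor_rna", subject = c("P1", "P2")), "absent"),
    "absent")
  neg <- flat; neg[1] <- -1
  expect_error(preprocessTranscriptomics(
    OmicBlock(neg, omic = "tumor_rna", subject = c("P1", "P2")), "hk1"),
    "negative")

  # two trials aligned to a common baseline median per gene
  v <- matrix(c(7, 7, 7, 11, 11, 11), nrow = 1, dimnames = list(c("g"), NULL))
  hk <- matrix(1, nrow = 1, ncol = 6, dimnames = list("hk", NULL))
  blk3 <- OmicBlock(rbind(v, hk), omic = "tumor_rna",
                    subject = paste0("P", 1:6),
                    trial = rep(c("A", "B"), each = 3))
  out3 <- preprocessTranscriptomics(blk3, "hk")
  expect_equal(median(out3@values["g", 1:3]), median(out3@values["g", 4:6]))
})

test_that("single-cell summaries follow the minimum-15-cell rule", {
  mm <- matrix(c(0, 3), 2, 1, dimnames = list(NULL, "CD25"))
  cells <- generateSingleCellFixture(c(14, 100), mm, seed = 5)
  blk <- summarizeSingleCell(cells, activationMarkers = "CD25",
                             metabolicMarkers = "CD25",
                             positivityThresholds = c(CD25 = 1.5))
  v <- blk@values
  # abundances always emitted and sum to 1 over the parent
  expect_equal(unname(v["abundance|cluster1", 1]), 14 / 114)
  expect_equal(sum(v[grep("^abundance", rownames(v)), 1]), 1, tolerance = 1e-9)
  # 14-cell cluster: only the frequency is calculated for that sample
  expect_true(is.na(v["pctpos|cluster1|CD25", 1]))
  expect_true(is.na(v["meanexpr|cluster1|CD25", 1]))
  expect_false(is.na(v["pctpos|cluster2|CD25", 1]))
})

test_that("percent-positive matches a direct count oracle", {
  cells <- data.frame(sample = "s1", cluster = "c1",
                      CD69 = c(rep(1, 15), rep(0, 5)))
  blk <- summarizeSingleCell(cells, activationMarkers = "CD69",
                             positivityThresholds = c(CD69 = 0.5))
  expect_equal(unname(blk@values["pctpos|c1|CD69", 1]), 100 * 15 / 20)
  allPos <- data.frame(sample = "s1", cluster = "c1", CD69 = rep(2, 100))
  blk2 <- summarizeSingleCell(allPos, activationMarkers = "CD69",
                              positivityThresholds = c(CD69 = 0.5))
  expect_equal(unname(blk2@values["pctpos|c1|CD69", 1]), 100)
  expect_error(summarizeSingleCell(cells, activationMarkers = "CD69"),
               "threshold missing")
})

test_that("assembly imputes column means and records the mask", {
  v <- matrix(c(1, 3, NA, 4, 4, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), NULL))
  blk <- serumBlock(v, subjects = c("P1", "P2", "P3"))
  tab <- assembleFeatures(list(blk), "BL")
  expect_equal(unname(featureValues(tab)["serum:f1", ]), c(1, 3, 2))
  expect_identical(sum(imputedMask(tab)), 1L)
  expect_true(imputedMask(tab)["serum:f1", "P3"])
  # imputation preserves the column (feature) mean exactly
  expect_equal(mean(featureValues(tab)["serum:f1", ]), mean(c(1, 3), na.rm = TRUE))
  expect_true(SummarizedExperiment::rowData(tab)[["constant"]][2])

  # no missing entries: identity with an empty mask
  full <- serumBlock(matrix(1:6, 2, dimnames = list(c("a", "b"), NULL)),
                     subjects = c("P1", "P2", "P3"))
  tabFull <- assembleFeatures(list(full), "BL")
  expect_identical(sum(imputedMask(tabFull)), 0L)

  allNA <- serumBlock(matrix(NA_real_, 1, 3, dimnames = list("x", NULL)),
                      subjects = c("P1", "P2", "P3"))
  expect_error(assembleFeatures(list(allNA), "BL"), "all subjects")
})

test_that("delta features are computed before imputation", {
  v <- matrix(c(2, 7, NA, 5, 10, 4), nrow = 1,
              dimnames = list("f", NULL))
  blk <- serumBlock(v, subjects = rep(c("P1", "P2", "P3"), 2),
                    timepoint = rep(c("BL", "C2"), each = 3))
  tab <- assembleFeatures(list(blk), "delta")
  d <- featureValues(tab)["serum:f", ]
  expect_equal(unname(d["P1"]), 3)             # 5 - 2
  expect_equal(unname(d["P2"]), 3)             # 10 - 7
  # P3 delta is missing (NA baseline) -> imputed to the delta column mean,
  # never fabricated from an imputed endpoint
  expect_equal(unname(d["P3"]), 3)
  expect_true(imputedMask(tab)["serum:f", "P3"])
})
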