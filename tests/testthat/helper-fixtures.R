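# Fixture builders shared across test files. All cohorts are generated in
# code; nothing is read from disk except where file IO itself is under test.

# A planted-effect table with a uniform standardized shift on unit-SD
# features (class means 0 vs `shift`).
shiftTemplate <- function(nPlanted = 10L, shift = 1) {
  data.frame(feature = sprintf("planted-%02d", seq_len(nPlanted)),
             mean_early = rep(0, nPlanted),
             sd_early = rep(1, nPlanted),
             mean_adv = rep(shift, nPlanted),
             sd_adv = rep(1, nPlanted),
             index = seq_len(nPlanted))
}

# Small z-scored cohort with planted features; shift = 0 gives a pure null.
makeCohort <- function(nFeatures = 60L, nPerClass = 30L, nPlanted = 10L,
                       shift = 1, seed = 1L) {
  planted <- if (nPlanted > 0L) shiftTemplate(nPlanted, shift) else NULL
  se <- simulateCohort(syntheticSpec(
    nFeatures = nFeatures, nPerClass = nPerClass, planted = planted,
    backgroundMeanRange = c(0, 0), backgroundSdRange = c(1, 1),
    seed = seed))
  normalizeExpression(se, "zscore")
}

# On-disk fixture (matrix + labels TSVs) for pipeline/CLI tests.
makePipelineFixture <- function(dir, seed = 1L) {
  se <- simulateCohort(syntheticSpec(
    nFeatures = 60, nPerClass = 20,
    planted = transform(plantedTemplate()[1:5, ], index = 1:5),
    effectMultiplier = 8, seed = seed))
  matrixPath <- file.path(dir, "matrix.tsv")
  labelsPath <- file.path(dir, "labels.tsv")
  writeExpressionMatrix(exprValues(se), matrixPath)
  writeStageLabels(setNames(stageLabels(se), colnames(se)), labelsPath)
  list(matrix = matrixPath, labels = labelsPath)
}

# Trivially separable cohort: every planted feature shifted by 6 SDs.
makeSeparable <- function(nPerClass = 25L, seed = 1L) {
  makeCohort(nFeatures = 12L, nPerClass = nPerClass, nPlanted = 4L,
             shift = 6, seed = seed)
}
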