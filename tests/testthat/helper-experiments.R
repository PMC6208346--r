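# Shared experiment protocols used by the calibration/recovery tests and
# mirrored by scripts/acceptance.R.

# Reduced GA configuration for search-quality experiments: per-phase budget
# with early stopping (see the methods vignette on the generation budget).
recoveryConfig <- function(seed) {
  ibcgaConfig(rStart = 5L, rEnd = 15L, nPop = 20L, gMax = 15L, k = 10L,
              gMaxMode = "per-phase", patience = 3L, seed = seed)
}

# Train-cohort selection + independent-cohort evaluation for one seed.
# Returns recall of planted features and held-out accuracy.
recoveryExperiment <- function(seed, nFeatures = 200L, nPerClass = 100L,
                               nPlanted = 10L, shift = 1) {
  tpl <- shiftTemplate(nPlanted, shift)
  train <- normalizeExpression(simulateCohort(syntheticSpec(
    nFeatures = nFeatures, nPerClass = nPerClass, planted = tpl,
    seed = seed)), "zscore")
  test <- normalizeExpression(simulateCohort(syntheticSpec(
    nFeatures = nFeatures, nPerClass = nPerClass, planted = tpl,
    seed = seed + 5000L)), "zscore")
  res <- runIBCGA(train, recoveryConfig(seed + 100L))
  sel <- res$best$featureIdx
  fit <- e1071::svm(t(exprValues(train))[, sel, drop = FALSE],
                    stageLabels(train), kernel = "radial",
                    cost = res$best$C, gamma = res$best$gamma,
                    scale = FALSE)
  pred <- predict(fit, t(exprValues(test))[, sel, drop = FALSE])
  list(recall = length(intersect(sel, seq_len(nPlanted))) / nPlanted,
       holdout = mean(pred == stageLabels(test)),
       fitness = res$best$fitness, size = res$best$r)
}

# Null-model counterpart: labels permuted before selection; accuracy is
# measured on a stratified held-out split never seen by the GA.
nullCalibrationExperiment <- function(seed, nFeatures = 100L,
                                      nPerClass = 60L) {
  se <- simulateCohort(syntheticSpec(nFeatures = nFeatures,
                                     nPerClass = nPerClass,
                                     planted = shiftTemplate(5, 1),
                                     seed = seed))
  se <- permuteLabels(se, seed = seed + 1L)
  se <- normalizeExpression(se, "zscore")
  split <- makeFolds(stageLabels(se), k = 3L, seed = seed + 2L)
  testIdx <- which(split$fold == 1L)
  trainIdx <- which(split$fold != 1L)
  train <- se[, trainIdx]
  cfg <- ibcgaConfig(rStart = 3L, rEnd = 6L, nPop = 10L, gMax = 6L,
                     k = 5L, seed = seed + 3L)
  res <- runIBCGA(train, cfg)
  sel <- res$best$featureIdx
  fit <- e1071::svm(t(exprValues(train))[, sel, drop = FALSE],
                    stageLabels(train), kernel = "radial",
                    cost = res$best$C, gamma = res$best$gamma,
                    scale = FALSE)
  pred <- predict(fit, t(exprValues(se))[testIdx, sel, drop = FALSE])
  mean(pred == stageLabels(se)[testIdx])
}

# MED/knockout coherence for one seed: one planted feature among noise.
rankingExperiment <- function(seed, nFeatures = 8L, nPerClass = 50L,
                              shift = 1.5) {
  se <- makeCohort(nFeatures = nFeatures, nPerClass = nPerClass,
                   nPlanted = 1L, shift = shift, seed = seed)
  folds <- makeFolds(stageLabels(se), k = 5L, seed = seed + 1L)
  med <- medRank(se, rownames(se), C = 1, gamma = 0.125, folds)
  ko <- knockoutAnalysis(se, rownames(se), C = 1, gamma = 0.125, folds)
  medRankOf <- match(rownames(se), med$feature)
  koRankOf <- rank(-ko$accuracyDiff)
  list(plantedTop = med$feature[1] == "planted-01",
       spearman = suppressWarnings(
         cor(medRankOf, koRankOf, method = "spearman")))
}
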