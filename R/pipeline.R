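#' End-to-end signature discovery pipeline
#'
#' Orchestrates the whole analysis: load (or accept) the expression matrix
#' and stage labels, normalize, run repeated IBCGA feature selection, rank
#' the selected signature by MED, run single-feature knockout, compute
#' per-group expression statistics, and evaluate information-gain +
#' standard-classifier baselines — all on one shared stratified fold
#' assignment. Writes \code{report.json}, \code{med.tsv},
#' \code{knockout.tsv}, \code{baselines.tsv}, \code{roc.csv} and a
#' \code{manifest.json} recording every seed and setting, so a run is fully
#' reproducible (outputs contain no timestamps and are byte-identical across
#' invocations with the same manifest).
#'
#' One global \code{seed} fans out to per-stage seeds through a fixed
#' documented scheme (offsets 1 = folds, 1000+i = GA run i, 5 = baselines),
#' so stages can be re-run independently.
#'
#' @param se a \linkS4class{StageExperiment}; alternatively give
#'   \code{matrixPath}/\code{labelsPath}.
#' @param matrixPath,labelsPath paths to a features-by-samples expression
#'   TSV/CSV and a two-column label file (see
#'   \code{\link{readExpressionMatrix}}, \code{\link{readStageLabels}}).
#' @param outdir output directory (created if missing); \code{NULL} skips
#'   writing files.
#' @param config an \code{\link{ibcgaConfig}} (its \code{seed} is overridden
#'   by \code{seed}).
#' @param normalization method for \code{\link{normalizeExpression}}.
#' @param k fold count shared by fitness, ranking, knockout and baselines.
#' @param seed global seed.
#' @param baselineFeatures how many information-gain features the baselines
#'   use (default 14).
#' @return invisible list: \code{report} (\linkS4class{SignatureReport}),
#'   \code{runs}, \code{med}, \code{knockout}, \code{groupStats},
#'   \code{baselines}, \code{roc}, \code{manifest}, \code{paths}.
#' @export
runPipeline <- function(se = NULL, matrixPath = NULL, labelsPath = NULL,
                        outdir = NULL, config = ibcgaConfig(),
                        normalization = "log2p1_zscore", k = 10L,
                        seed = 1L, baselineFeatures = 14L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(se)) {
    stage("load", {
      if (is.null(matrixPath) || is.null(labelsPath))
        stop("provide either `se` or both `matrixPath` and `labelsPath`")
      if (!file.exists(matrixPath)) stop("matrix file not found: ",
                                         matrixPath)
      if (!file.exists(labelsPath)) stop("label file not found: ",
                                         labelsPath)
      m <- readExpressionMatrix(matrixPath)
      lab <- readStageLabels(labelsPath)
      se <- StageExperiment(m, lab)
    })
  }
  config$seed <- as.integer(seed)
  config$k <- as.integer(k)
  se <- stage("normalize", normalizeExpression(se, normalization))
  folds <- stage("folds",
                 makeFolds(stageLabels(se), k = k,
                           seed = deriveSeed(seed, 1L)))
  runs <- stage("select", repeatedRuns(se, config, folds = folds))
  best <- runs$best
  cv <- stage("evaluate",
              crossValidate(se, best$featureIdx, best$C, best$gamma, folds))
  med <- stage("rank", if (length(best$features) >= 2L)
    medRank(se, best$features, best$C, best$gamma, folds)
    else NULL)
  ko <- stage("knockout", if (length(best$features) >= 2L)
    knockoutAnalysis(se, best$features, best$C, best$gamma, folds)
    else NULL)
  gs <- stage("group-stats", groupStats(se, best$features))
  nb <- min(baselineFeatures, nrow(se))
  igFeatures <- stage("info-gain", infoGainRank(se, k = nb))
  baselines <- stage("baselines",
                     runBaselines(se, igFeatures, folds,
                                  seed = deriveSeed(seed, 5L)))

  medVec <- if (is.null(med)) numeric(0) else
    stats::setNames(med$med, med$feature)
  koVec <- if (is.null(ko)) numeric(0) else
    stats::setNames(ko$accuracyDiff, ko$feature)
  report <- SignatureReport(
    features = best$features, medScores = medVec, knockoutDiffs = koVec,
    groupStats = gs,
    svmParams = c(C = best$C, gamma = best$gamma),
    metrics = unclass(cv)[c("counts", "acc", "sn", "sp", "mcc", "auc",
                            "foldAccuracies", "fitness")],
    metadata = list(normalization = normalization, seed = seed, k = k,
                    meanFitness = runs$meanFitness,
                    sdFitness = runs$sdFitness,
                    runFitnesses = runs$fitnesses,
                    signatureSize = length(best$features), r = best$r))

  manifest <- list(
    seed = seed,
    stageSeeds = list(folds = deriveSeed(seed, 1L),
                      gaRuns = vapply(seq_len(config$runs), function(i)
                        deriveSeed(seed, 1000L + i), numeric(1)),
                      baselines = deriveSeed(seed, 5L)),
    config = unclass(config), normalization = normalization, k = k,
    baselineFeatures = nb,
    inputs = list(matrixPath = matrixPath, labelsPath = labelsPath,
                  nFeatures = nrow(se), nSamples = ncol(se)))

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(report = file.path(outdir, "report.json"),
                  med = file.path(outdir, "med.tsv"),
                  knockout = file.path(outdir, "knockout.tsv"),
                  baselines = file.path(outdir, "baselines.tsv"),
                  roc = file.path(outdir, "roc.csv"),
                  manifest = file.path(outdir, "manifest.json"))
    writeSignatureReport(report, paths$report)
    if (!is.null(med))
      utils::write.table(med, paths$med, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    if (!is.null(ko))
      utils::write.table(ko, paths$knockout, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    utils::write.table(baselines, paths$baselines, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeRocPoints(rocAuc(cv$scores, stageLabels(se)), paths$roc)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = I(17), null = "null", pretty = TRUE)
  }
  invisible(list(report = report, runs = runs, cv = cv, med = med,
                 knockout = ko, groupStats = gs, baselines = baselines,
                 manifest = manifest, paths = paths, se = se,
                 folds = folds))
}

#' A reduced configuration for quick runs
#'
#' Small population / short budget settings for smoke tests and desk-scale
#' experimentation.
#' @param seed master seed.
#' @return an \code{\link{ibcgaConfig}}.
#' @export
fastConfig <- function(seed = 1L) {
  ibcgaConfig(rStart = 3L, rEnd = 8L, nPop = 10L, gMax = 6L, k = 5L,
              seed = seed)
}
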