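#' Reference template of planted group means
#'
#' Per-group expression summaries (mean and SD on a log2-like scale, per
#' stage group) for ten miRNAs repeatedly reported as stage-informative in
#' TCGA breast-cancer cohorts. These are the default planted effects of
#' \code{\link{simulateCohort}}: small mean shifts (0 to ~0.4 units) on SDs
#' between 0.4 and 1.4, i.e. standardized effect sizes well under 0.5 —
#' deliberately hard, realistic targets.
#'
#' @return a data.frame with columns \code{feature}, \code{mean_early},
#'   \code{sd_early}, \code{mean_adv}, \code{sd_adv} (10 rows).
#' @export
plantedTemplate <- function() {
  data.frame(
    feature = c("hsa-miR-200c", "hsa-miR-503", "hsa-miR-1307",
                "hsa-miR-361", "hsa-miR-212", "hsa-miR-592",
                "hsa-miR-1185-1", "hsa-miR-146b", "hsa-miR-1468",
                "hsa-miR-769"),
    mean_early = c(13.34, 3.44, 10.16, 8.35, 2.20, 1.93, 0.24, 9.03, 2.50,
                   4.88),
    sd_early = c(0.94, 1.28, 1.04, 0.57, 0.83, 1.11, 0.39, 0.94, 1.10,
                 0.70),
    mean_adv = c(13.28, 3.80, 9.93, 8.30, 2.20, 1.80, 0.35, 9.20, 2.45,
                 4.75),
    sd_adv = c(0.77, 1.39, 1.12, 0.55, 0.80, 1.11, 0.39, 0.96, 1.06,
               0.77),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic two-class cohort
#'
#' @param nFeatures total number of features (default 503).
#' @param nPerClass samples per class (default 193; must be >= 2).
#' @param planted data.frame like \code{\link{plantedTemplate}()}, optionally
#'   with an \code{index} column giving the feature row each planted effect
#'   occupies (defaults to the first rows). All SDs must be positive.
#' @param backgroundMeanRange,backgroundSdRange intervals from which each
#'   background feature draws its class-independent mean and SD (defaults
#'   [0, 14] and [0.4, 1.4], the span of the template values).
#' @param effectMultiplier scales every planted between-class mean shift
#'   about its midpoint (1 = template effect sizes).
#' @param seed integer seed; the cohort is bit-reproducible from it.
#' @return a list of class \code{syntheticSpec}.
#' @export
syntheticSpec <- function(nFeatures = 503L, nPerClass = 193L,
                          planted = plantedTemplate(),
                          backgroundMeanRange = c(0, 14),
                          backgroundSdRange = c(0.4, 1.4),
                          effectMultiplier = 1, seed = 1L) {
  if (nPerClass < 2L) stop("nPerClass must be >= 2")
  if (!is.null(planted) && nrow(planted) > 0L) {
    if (is.null(planted$index)) planted$index <- seq_len(nrow(planted))
    if (anyDuplicated(planted$index) || any(planted$index > nFeatures) ||
        any(planted$index < 1L))
      stop("planted indices must be unique and within 1..nFeatures")
    if (any(planted$sd_early <= 0) || any(planted$sd_adv <= 0))
      stop("planted SDs must be positive")
    if (is.null(planted$feature))
      planted$feature <- sprintf("planted-%02d", seq_len(nrow(planted)))
  }
  structure(list(nFeatures = as.integer(nFeatures),
                 nPerClass = as.integer(nPerClass), planted = planted,
                 backgroundMeanRange = backgroundMeanRange,
                 backgroundSdRange = backgroundSdRange,
                 effectMultiplier = effectMultiplier,
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Simulate a labeled two-class expression cohort
#'
#' Generates a balanced early/advanced cohort on a log2-like scale. Planted
#' features are Gaussian with class-specific (mean, SD) from the spec;
#' background features are Gaussian with a single class-independent mean and
#' SD drawn per feature from the spec's ranges, so they carry no class
#' signal. Values are not clipped at zero: downstream normalization makes
#' slight negativity on this scale irrelevant.
#'
#' The planted feature indices (ground truth) are recorded in
#' \code{metadata()$planted}, the spec in \code{metadata()$syntheticSpec}.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return a \linkS4class{StageExperiment} with \code{2 * nPerClass} samples.
#' @examples
#' se <- simulateCohort(syntheticSpec(nFeatures = 50, nPerClass = 20))
#' se
#' @export
simulateCohort <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "syntheticSpec"))
  withLocalSeed(spec$seed, {
    p <- spec$nFeatures
    n <- 2L * spec$nPerClass
    early <- seq_len(spec$nPerClass)
    adv <- spec$nPerClass + seq_len(spec$nPerClass)
    featureIds <- sprintf("mir-sim-%04d", seq_len(p))
    planted <- spec$planted
    if (!is.null(planted) && nrow(planted) > 0L)
      featureIds[planted$index] <- planted$feature
    m <- matrix(NA_real_, p, n,
                dimnames = list(featureIds, sprintf("sample-%04d",
                                                    seq_len(n))))
    bgMean <- stats::runif(p, spec$backgroundMeanRange[1L],
                           spec$backgroundMeanRange[2L])
    bgSd <- stats::runif(p, spec$backgroundSdRange[1L],
                         spec$backgroundSdRange[2L])
    for (i in seq_len(p))
      m[i, ] <- stats::rnorm(n, bgMean[i], bgSd[i])
    if (!is.null(planted) && nrow(planted) > 0L) {
      for (j in seq_len(nrow(planted))) {
        i <- planted$index[j]
        mid <- (planted$mean_early[j] + planted$mean_adv[j]) / 2
        half <- (planted$mean_adv[j] - planted$mean_early[j]) / 2 *
          spec$effectMultiplier
        m[i, early] <- stats::rnorm(spec$nPerClass, mid - half,
                                    planted$sd_early[j])
        m[i, adv] <- stats::rnorm(spec$nPerClass, mid + half,
                                  planted$sd_adv[j])
      }
    }
    labels <- factor(rep(stageLevels, each = spec$nPerClass),
                     levels = stageLevels)
    se <- StageExperiment(m, labels)
    S4Vectors::metadata(se)$planted <-
      if (is.null(planted)) integer(0) else planted$index
    S4Vectors::metadata(se)$plantedFeatures <-
      if (is.null(planted)) character(0) else planted$feature
    S4Vectors::metadata(se)$syntheticSpec <- unclass(spec)
    se
  })
}

#' Permute stage labels (null cohort)
#'
#' Uniformly permutes the stage labels while leaving the expression matrix
#' untouched — the standard null model for calibration checks.
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param seed integer seed (deterministic permutation).
#' @return a \code{StageExperiment} with permuted labels.
#' @export
permuteLabels <- function(se, seed = 1L) {
  stopifnot(is(se, "StageExperiment"))
  withLocalSeed(seed, {
    perm <- sample.int(ncol(se))
    SummarizedExperiment::colData(se)$stage <- stageLabels(se)[perm]
    se
  })
}
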