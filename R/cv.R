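#' Stratified cross-validation folds
#'
#' Partitions samples into \code{k} folds, stratified by class: each fold's
#' class counts differ from an even split by at most one sample, and the
#' per-class remainders are spread greedily over the currently smallest folds
#' so overall fold sizes also stay within one of each other.
#'
#' @param labels class labels (factor/character/0-1 vector).
#' @param k number of folds (>= 2, <= number of samples).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return list of class \code{foldAssignment}: \code{k}, integer
#'   \code{fold} per sample, \code{seed}.
#' @export
makeFolds <- function(labels, k = 10L, seed = 1L) {
  y <- asStageFactor(labels)
  n <- length(y)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds number of samples (", n, ")")
  withLocalSeed(seed, {
    fold <- integer(n)
    foldTotal <- integer(k)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      nc <- length(idx)
      base <- nc %/% k
      rem <- nc %% k
      sizes <- rep(base, k)
      if (rem > 0L) {
        # give remainders to the folds currently smallest (random ties)
        pick <- order(foldTotal, stats::runif(k))[seq_len(rem)]
        sizes[pick] <- sizes[pick] + 1L
      }
      fold[idx] <- rep.int(seq_len(k), sizes)
      foldTotal <- foldTotal + sizes
    }
    structure(list(k = as.integer(k), fold = fold, seed = as.integer(seed)),
              class = "foldAssignment")
  })
}

#' Train an RBF SVM and predict held-out samples
#'
#' Fits a soft-margin SVM with Gaussian (RBF) kernel on the training samples
#' restricted to a feature subset, and returns hard labels plus signed
#' decision scores (distance to the hyperplane, oriented so larger =
#' more advanced-like) for the test samples. No additional scaling is applied
#' inside the SVM; normalize upstream. Duplicating a feature changes the
#' kernel's effective length scale (features are not re-weighted), which is
#' the standard RBF convention.
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param trainIdx,testIdx sample (column) indices.
#' @param features feature subset: indices or row names (non-empty).
#' @param C SVM cost parameter (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return list: \code{labels} (factor early/advanced) and \code{scores}
#'   (numeric) for the test samples.
#' @export
trainPredictSVM <- function(se, trainIdx, testIdx, features, C = 1,
                            gamma = 0.1) {
  X <- t(exprValues(se))
  y <- stageLabels(se)
  svmPredict(X, y, trainIdx, testIdx, resolveFeatures(se, features), C,
             gamma)
}

resolveFeatures <- function(se, features) {
  if (is.character(features)) {
    idx <- match(features, rownames(se))
    if (anyNA(idx))
      stop("unknown feature(s): ",
           paste(features[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(features)
}

# core fit/predict on a samples-x-features matrix (kept internal & minimal:
# called thousands of times from the GA loop)
svmPredict <- function(X, y, trainIdx, testIdx, featIdx, C, gamma) {
  if (length(featIdx) == 0L) stop("feature subset must be non-empty")
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive")
  ytr <- droplevels(y[trainIdx])
  if (nlevels(ytr) < 2L) stop("training set contains a single class")
  fit <- e1071::svm(x = X[trainIdx, featIdx, drop = FALSE],
                    y = y[trainIdx], kernel = "radial", cost = C,
                    gamma = gamma, scale = FALSE)
  pr <- predict(fit, X[testIdx, featIdx, drop = FALSE],
                decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (startsWith(colnames(dv)[1L], "advanced")) 1 else -1
  list(labels = factor(as.character(pr), levels = stageLevels),
       scores = sgn * as.numeric(dv[, 1L]))
}

#' Cross-validate an SVM on a feature subset
#'
#' For each fold, trains on the remaining folds and predicts the held-out
#' fold; predictions are pooled over folds, metrics are computed on the
#' pooled confusion table, and AUC on the pooled decision scores. The GA
#' fitness is the pooled accuracy in percent.
#'
#' @inheritParams trainPredictSVM
#' @param folds a \code{\link{makeFolds}} assignment for the dataset.
#' @return list of class \code{CVResult}: \code{counts}, \code{acc},
#'   \code{sn}, \code{sp}, \code{mcc}, \code{auc}, \code{foldAccuracies},
#'   \code{fitness} (= 100 * acc), \code{params}, \code{features}.
#' @export
crossValidate <- function(se, features, C = 1, gamma = 0.1, folds) {
  X <- t(exprValues(se))
  y <- stageLabels(se)
  featIdx <- resolveFeatures(se, features)
  cvCore(X, y, featIdx, C, gamma, folds,
         featureNames = rownames(se)[featIdx])
}

cvCore <- function(X, y, featIdx, C, gamma, folds, featureNames = NULL) {
  stopifnot(inherits(folds, "foldAssignment"),
            length(folds$fold) == nrow(X))
  n <- nrow(X)
  predLab <- factor(rep(NA_character_, n), levels = stageLevels)
  scores <- numeric(n)
  foldAcc <- numeric(folds$k)
  for (f in seq_len(folds$k)) {
    te <- which(folds$fold == f)
    tr <- which(folds$fold != f)
    out <- svmPredict(X, y, tr, te, featIdx, C, gamma)
    predLab[te] <- out$labels
    scores[te] <- out$scores
    foldAcc[f] <- mean(out$labels == y[te])
  }
  counts <- confusionCounts(y, predLab)
  m <- classMetrics(counts)
  roc <- rocAuc(scores, y)
  structure(list(counts = counts, acc = m$acc, sn = m$sn, sp = m$sp,
                 mcc = m$mcc, auc = roc$auc, foldAccuracies = foldAcc,
                 fitness = 100 * m$acc,
                 params = c(C = C, gamma = gamma),
                 features = featureNames %||% featIdx,
                 scores = scores),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf(
    "CVResult: acc = %.4f, sn = %.4f, sp = %.4f, mcc = %.4f, auc = %.4f\n",
    x$acc, x$sn, x$sp, x$mcc, x$auc))
  cat("  features:", length(x$features), " C =", x$params[["C"]],
      " gamma =", x$params[["gamma"]], "\n")
  invisible(x)
}

#' Jackknife (leave-one-out) accuracy
#'
#' Trains on \code{n - 1} samples and predicts the held-out sample, for every
#' sample in turn; equivalent to \code{n}-fold cross-validation.
#'
#' @inheritParams trainPredictSVM
#' @return leave-one-out accuracy in [0, 1].
#' @export
jackknifeAccuracy <- function(se, features, C = 1, gamma = 0.1) {
  n <- ncol(se)
  if (n < 3L) stop("jackknife needs at least 3 samples")
  X <- t(exprValues(se))
  y <- stageLabels(se)
  featIdx <- resolveFeatures(se, features)
  correct <- logical(n)
  for (i in seq_len(n)) {
    out <- svmPredict(X, y, setdiff(seq_len(n), i), i, featIdx, C, gamma)
    correct[i] <- out$labels == y[i]
  }
  mean(correct)
}
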