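#' Main-effect-difference (MED) ranking of a signature
#'
#' Ranks signature members by their contribution to prediction accuracy
#' using a 2-level orthogonal experimental design: each OA factor is one
#' feature (level 1 = included, level 0 = excluded), each OA row is a
#' cross-validated SVM experiment on the included subset, and a feature's
#' MED score is the difference between its mean row fitness at level 1 and
#' at level 0. Rows with no included feature score 0. Features are ranked by
#' descending MED, ties broken lexicographically by feature ID.
#'
#' For m factors the array has \eqn{2^{\lceil \log_2(m+1) \rceil}} rows, so
#' a 34-feature signature needs 64 experiments.
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param signature character vector of >= 2 feature IDs.
#' @param C,gamma SVM parameters of the selected model (kept fixed across
#'   experiments so the design isolates feature contributions).
#' @param folds a \code{\link{makeFolds}} assignment, identical for every
#'   experiment.
#' @param fitnessFn optional override: a function \code{subset -> fitness}
#'   taking a character vector of included features (used by calibration
#'   tests; default = pooled CV accuracy in percent).
#' @return data.frame of class \code{medTable} with columns \code{rank},
#'   \code{feature}, \code{med}, sorted by rank.
#' @export
medRank <- function(se, signature, C = 1, gamma = 0.1, folds = NULL,
                    fitnessFn = NULL) {
  signature <- as.character(signature)
  m <- length(signature)
  if (m < 2L) stop("MED ranking needs at least 2 features")
  if (is.null(fitnessFn)) {
    stopifnot(is(se, "StageExperiment"))
    if (is.null(folds)) folds <- makeFolds(stageLabels(se), k = 10L)
    X <- t(exprValues(se))
    y <- stageLabels(se)
    featIdx <- resolveFeatures(se, signature)
    fitnessFn <- function(subset) {
      if (length(subset) == 0L) return(0)
      idx <- featIdx[match(subset, signature)]
      res <- tryCatch(cvCore(X, y, idx, C, gamma, folds),
                      error = function(e) NULL)
      if (is.null(res)) 0 else res$fitness
    }
  }
  oa <- buildOA(m)$array
  rowFit <- vapply(seq_len(nrow(oa)), function(i)
    fitnessFn(signature[oa[i, ] == 1L]), numeric(1))
  med <- vapply(seq_len(m), function(j)
    mean(rowFit[oa[, j] == 1L]) - mean(rowFit[oa[, j] == 0L]), numeric(1))
  ord <- order(-med, signature)
  out <- data.frame(rank = seq_len(m), feature = signature[ord],
                    med = med[ord], stringsAsFactors = FALSE)
  class(out) <- c("medTable", "data.frame")
  out
}

#' Single-feature knockout analysis
#'
#' Measures each signature member's contribution as the drop in pooled
#' cross-validation accuracy (percentage points) when that one feature is
#' removed, with the SVM parameters and folds held fixed throughout:
#' \eqn{\Delta ACC(i) = ACC(signature) - ACC(signature \setminus \{i\})}.
#'
#' @inheritParams medRank
#' @return data.frame of class \code{knockoutTable} with columns
#'   \code{feature}, \code{accuracyDiff} (percentage points), plus the
#'   full-signature accuracy in \code{attr(, "fullAccuracy")}.
#' @export
knockoutAnalysis <- function(se, signature, C = 1, gamma = 0.1,
                             folds = NULL) {
  stopifnot(is(se, "StageExperiment"))
  signature <- as.character(signature)
  if (length(signature) < 2L) stop("knockout needs at least 2 features")
  if (is.null(folds)) folds <- makeFolds(stageLabels(se), k = 10L)
  X <- t(exprValues(se))
  y <- stageLabels(se)
  featIdx <- resolveFeatures(se, signature)
  accOf <- function(idx) 100 * cvCore(X, y, idx, C, gamma, folds)$acc
  full <- accOf(featIdx)
  diffs <- vapply(seq_along(featIdx), function(i)
    full - accOf(featIdx[-i]), numeric(1))
  out <- data.frame(feature = signature, accuracyDiff = diffs,
                    stringsAsFactors = FALSE)
  attr(out, "fullAccuracy") <- full
  class(out) <- c("knockoutTable", "data.frame")
  out
}

#' Per-group expression statistics
#'
#' Sample mean and SD (denominator n - 1) per stage group for the requested
#' features, computed on the pre-normalization scale when it was retained by
#' \code{\link{normalizeExpression}} (otherwise on the stored scale; see the
#' \code{scale} attribute).
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param features feature IDs or indices (default: all).
#' @return data.frame with columns \code{feature}, \code{mean_early},
#'   \code{sd_early}, \code{mean_adv}, \code{sd_adv}; the value scale is in
#'   \code{attr(, "scale")}.
#' @export
groupStats <- function(se, features = rownames(se)) {
  stopifnot(is(se, "StageExperiment"))
  idx <- resolveFeatures(se, features)
  m <- rawValues(se)
  y <- stageLabels(se)
  if (any(table(y) < 2L)) stop("each class needs >= 2 samples for an SD")
  e <- y == "early"
  sub <- m[idx, , drop = FALSE]
  out <- data.frame(
    feature = rownames(se)[idx],
    mean_early = rowMeans(sub[, e, drop = FALSE]),
    sd_early = apply(sub[, e, drop = FALSE], 1L, stats::sd),
    mean_adv = rowMeans(sub[, !e, drop = FALSE]),
    sd_adv = apply(sub[, !e, drop = FALSE], 1L, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "scale") <- attr(m, "scale")
  out
}

entropyBits <- function(y) {
  p <- tabulate(as.integer(factor(y)))
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

# Fayyad-Irani MDL recursive binary discretization; returns cut values
mdlCutpoints <- function(x, y) {
  ord <- order(x)
  recurse <- function(xs, ys) {
    n <- length(xs)
    if (n < 4L) return(numeric(0))
    boundary <- which(diff(xs) > 0)
    if (length(boundary) == 0L) return(numeric(0))
    E <- entropyBits(ys)
    k <- length(unique(ys))
    best <- NULL
    bestEw <- Inf
    for (b in boundary) {
      e1 <- entropyBits(ys[1:b])
      e2 <- entropyBits(ys[(b + 1L):n])
      ew <- (b * e1 + (n - b) * e2) / n
      if (ew < bestEw) {
        bestEw <- ew
        best <- list(b = b, e1 = e1, e2 = e2)
      }
    }
    gain <- E - bestEw
    k1 <- length(unique(ys[1:best$b]))
    k2 <- length(unique(ys[(best$b + 1L):n]))
    delta <- log2(3^k - 2) - (k * E - k1 * best$e1 - k2 * best$e2)
    if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    cut <- (xs[best$b] + xs[best$b + 1L]) / 2
    c(recurse(xs[1:best$b], ys[1:best$b]), cut,
      recurse(xs[(best$b + 1L):n], ys[(best$b + 1L):n]))
  }
  sort(recurse(x[ord], y[ord]))
}

#' Information gain of one feature for the stage labels
#'
#' Discretizes the feature by entropy-minimizing MDL binning (Fayyad-Irani
#' recursive binary splits); when the MDL criterion accepts no split, falls
#' back to 10 equal-frequency bins. Returns
#' \eqn{IG = H(labels) - H(labels | bin)} in bits.
#'
#' @param x numeric feature values.
#' @param y class labels.
#' @return information gain in bits (>= 0).
#' @export
infoGain <- function(x, y) {
  y <- as.factor(y)
  cuts <- mdlCutpoints(x, y)
  if (length(cuts) == 0L) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = 11L)))
    if (length(br) < 3L) return(0)
    bins <- cut(x, breaks = br, include.lowest = TRUE)
  } else {
    bins <- cut(x, breaks = c(-Inf, cuts, Inf))
  }
  H <- entropyBits(y)
  Hcond <- 0
  n <- length(y)
  for (lv in levels(bins)) {
    inBin <- bins == lv
    nb <- sum(inBin)
    if (nb > 0L) Hcond <- Hcond + nb / n * entropyBits(y[inBin])
  }
  max(H - Hcond, 0)
}

#' Rank features by information gain
#'
#' The attribute-ranking baseline: computes \code{\link{infoGain}} for every
#' feature against the stage labels and returns the \code{k} largest.
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param k how many features to return (<= number of features).
#' @return character vector of \code{k} feature IDs, in decreasing
#'   information-gain order, with the gains as a \code{gain} attribute.
#' @export
infoGainRank <- function(se, k = 14L) {
  stopifnot(is(se, "StageExperiment"))
  if (k > nrow(se)) stop("k exceeds number of features")
  m <- exprValues(se)
  y <- stageLabels(se)
  ig <- apply(m, 1L, infoGain, y = y)
  ord <- order(-ig, rownames(se))
  out <- rownames(se)[ord][seq_len(k)]
  attr(out, "gain") <- unname(ig[ord][seq_len(k)])
  out
}

#' Standard-classifier baselines under shared folds
#'
#' Evaluates random forest, a multilayer perceptron, a linear-kernel SVM, a
#' naive Bayes classifier and a CART decision tree on one feature subset
#' under identical stratified folds, pooling held-out predictions per
#' classifier. All classifiers are delegated to their standard
#' implementations at (near-)default settings; failures of one classifier
#' are reported as NA rows without aborting the others.
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param features the feature subset (IDs or indices), e.g. an
#'   information-gain selection.
#' @param folds a \code{\link{makeFolds}} assignment.
#' @param seed seed for the stochastic learners (forest, MLP).
#' @return data.frame with columns \code{method}, \code{acc}, \code{sn},
#'   \code{sp}, \code{mcc}.
#' @export
runBaselines <- function(se, features, folds = NULL, seed = 1L) {
  stopifnot(is(se, "StageExperiment"))
  idx <- resolveFeatures(se, features)
  if (length(idx) == 0L) stop("feature subset must be non-empty")
  if (is.null(folds)) folds <- makeFolds(stageLabels(se), k = 10L)
  X <- t(exprValues(se))[, idx, drop = FALSE]
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- stageLabels(se)
  df <- data.frame(X, stage = y)
  n <- nrow(df)

  fitters <- list(
    `random forest` = function(tr, te) {
      fit <- randomForest::randomForest(stage ~ ., data = df[tr, ])
      predict(fit, df[te, ])
    },
    `multilayer perceptron` = function(tr, te) {
      fit <- nnet::nnet(stage ~ ., data = df[tr, ], size = 5L,
                        decay = 0.01, maxit = 200L, trace = FALSE)
      factor(predict(fit, df[te, , drop = FALSE], type = "class"),
             levels = stageLevels)
    },
    `linear SVM` = function(tr, te) {
      fit <- e1071::svm(stage ~ ., data = df[tr, ], kernel = "linear")
      predict(fit, df[te, ])
    },
    `naive Bayes` = function(tr, te) {
      fit <- e1071::naiveBayes(stage ~ ., data = df[tr, ])
      predict(fit, df[te, ])
    },
    `decision tree` = function(tr, te) {
      fit <- rpart::rpart(stage ~ ., data = df[tr, ], method = "class")
      predict(fit, df[te, ], type = "class")
    })

  rows <- lapply(names(fitters), function(nm) {
    pred <- tryCatch(withLocalSeed(seed, {
      out <- factor(rep(NA_character_, n), levels = stageLevels)
      for (f in seq_len(folds$k)) {
        te <- which(folds$fold == f)
        tr <- which(folds$fold != f)
        out[te] <- fitters[[nm]](tr, te)
      }
      out
    }), error = function(e) {
      warning(nm, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(pred))
      return(data.frame(method = nm, acc = NA_real_, sn = NA_real_,
                        sp = NA_real_, mcc = NA_real_))
    m <- classMetrics(confusionCounts(y, pred))
    data.frame(method = nm, acc = m$acc, sn = m$sn, sp = m$sp,
               mcc = m$mcc)
  })
  do.call(rbind, rows)
}
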