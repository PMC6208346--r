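test_that("confusion counts match a brute-force element-wise tally", {
  ct <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(unlist(ct[c("TP", "FN", "TN", "FP")]),
                   c(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  ct2 <- confusionCounts(c(1, 0, 1), c(1, 0, 1))
  expect_identical(ct2$FP + ct2$FN, 0L)
  expect_error(confusionCounts(c(1, 0), c(1, 0, 1)), "mismatch")

  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    yt <- rbinom(n, 1, 0.5)
    yp <- rbinom(n, 1, 0.5)
    ct <- confusionCounts(yt, yp)
    # independent oracle: loop over pairs
    tp <- tn <- fp <- fn <- 0L
    for (j in seq_len(n)) {
      if (yt[j] == 1 && yp[j] == 1) tp <- tp + 1L
      else if (yt[j] == 0 && yp[j] == 0) tn <- tn + 1L
      else if (yt[j] == 0 && yp[j] == 1) fp <- fp + 1L
      else fn <- fn + 1L
    }
    expect_identical(unlist(ct), c(TP = tp, TN = tn, FP = fp, FN = fn))
    expect_identical(ct$TP + ct$TN + ct$FP + ct$FN, n)
  }
})

test_that("classification metrics agree with closed forms and oracles", {
  perfect <- classMetrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_identical(unlist(perfect), c(acc = 1, sn = 1, sp = 1, mcc = 1))
  coin <- classMetrics(list(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_identical(coin$acc, 0.5)
  expect_identical(coin$mcc, 0)
  m <- classMetrics(list(TP = 80, FN = 20, TN = 70, FP = 30))
  expect_equal(m$mcc, 5000 / sqrt(110 * 100 * 100 * 90), tolerance = 1e-12)
  # MCC equals the Pearson correlation of the two binary indicator vectors
  yt <- rep(c(1, 1, 0, 0), times = c(80, 20, 70, 30))
  yp <- rep(c(1, 0, 0, 1), times = c(80, 20, 70, 30))
  expect_equal(m$mcc, cor(yt, yp), tolerance = 1e-12)

  expect_error(classMetrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "no evaluated samples")
  degenerate <- classMetrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(degenerate$sn))
  expect_identical(degenerate$mcc, 0)
})

test_that("metrics match an independent brute-force oracle on random tables", {
  set.seed(42)
  for (i in 1:1000) {
    cts <- as.list(sample(0:200, 4, replace = TRUE))
    names(cts) <- c("TP", "TN", "FP", "FN")
    if (sum(unlist(cts)) == 0) next
    m <- classMetrics(cts)
    tp <- cts$TP; tn <- cts$TN; fp <- cts$FP; fn <- cts$FN
    expect_identical(m$acc, (tp + tn) / (tp + tn + fp + fn))
    if (tp + fn > 0) expect_identical(m$sn, tp / (tp + fn))
    if (tn + fp > 0) expect_identical(m$sp, tn / (tn + fp))
    den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
    mccOracle <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
    expect_identical(m$mcc, mccOracle)
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
    # label-swap symmetry
    swapped <- classMetrics(list(TP = tn, TN = tp, FP = fn, FN = fp))
    expect_equal(swapped$mcc, m$mcc, tolerance = 1e-12)
  }
})

test_that("stratified folds partition samples with balanced classes", {
  lab <- rep(c("early", "advanced"), each = 10)
  f <- makeFolds(lab, k = 10, seed = 3)
  expect_identical(sort(unique(f$fold)), 1:10)
  for (i in 1:10) {
    idx <- f$fold == i
    expect_identical(sum(idx & lab == "early"), 1L)
    expect_identical(sum(idx & lab == "advanced"), 1L)
  }
  expect_identical(makeFolds(lab, k = 10, seed = 3)$fold, f$fold)
  expect_false(identical(makeFolds(lab, k = 10, seed = 4)$fold, f$fold))
  expect_error(makeFolds(lab, k = 21), "exceeds")

  # the reference cohort shape: 193/193 at k = 5
  lab2 <- rep(c("early", "advanced"), each = 193)
  f5 <- makeFolds(lab2, k = 5, seed = 1)
  sizes <- tabulate(f5$fold, 5)
  expect_true(all(sizes %in% c(77L, 78L)))
  for (i in 1:5) {
    ne <- sum(f5$fold == i & lab2 == "early")
    na <- sum(f5$fold == i & lab2 == "advanced")
    expect_lte(abs(ne - na), 1L)
  }
})

test_that("the SVM separates well-separated clouds and is label-honest", {
  se <- makeSeparable(nPerClass = 50, seed = 1)
  folds <- makeFolds(stageLabels(se), k = 5, seed = 1)
  tr <- which(folds$fold != 1)
  te <- which(folds$fold == 1)
  out <- trainPredictSVM(se, tr, te, features = 1:4, C = 1, gamma = 0.1)
  expect_identical(as.character(out$labels),
                   as.character(stageLabels(se)[te]))
  # scores oriented so larger = more advanced-like
  expect_gt(min(out$scores[stageLabels(se)[te] == "advanced"]),
            max(out$scores[stageLabels(se)[te] == "early"]))

  # permuted labels give chance-level held-out accuracy
  null <- permuteLabels(makeCohort(nFeatures = 20, nPerClass = 100,
                                   shift = 2, seed = 2), seed = 5)
  nf <- makeFolds(stageLabels(null), k = 2, seed = 1)
  o2 <- trainPredictSVM(null, which(nf$fold == 1), which(nf$fold == 2),
                        1:20, C = 1, gamma = 0.05)
  acc <- mean(o2$labels == stageLabels(null)[nf$fold == 2])
  expect_lt(abs(acc - 0.5), 0.12)

  expect_error(trainPredictSVM(se, which(stageLabels(se) == "early"), te,
                               1:4, 1, 0.1), "single class")
  expect_error(trainPredictSVM(se, tr, te, integer(0), 1, 0.1),
               "non-empty")
  expect_error(trainPredictSVM(se, tr, te, 1:4, C = -1, gamma = 0.1),
               "positive")
})

test_that("duplicating every feature is equivalent to halving gamma", {
  se <- makeCohort(nFeatures = 6, nPerClass = 25, nPlanted = 3, shift = 1.2,
                   seed = 3)
  m <- exprValues(se)
  dup <- rbind(m, `rownames<-`(m, paste0(rownames(m), "-copy")))
  seDup <- StageExperiment(dup, stageLabels(se))
  folds <- makeFolds(stageLabels(se), k = 5, seed = 2)
  tr <- which(folds$fold != 1); te <- which(folds$fold == 1)
  a <- trainPredictSVM(se, tr, te, 1:6, C = 2, gamma = 0.2)
  b <- trainPredictSVM(seDup, tr, te, 1:12, C = 2, gamma = 0.1)
  expect_identical(as.character(a$labels), as.character(b$labels))
  expect_equal(a$scores, b$scores, tolerance = 1e-6)
})

test_that("cross-validation pools predictions and conserves counts", {
  se <- makeSeparable(nPerClass = 25, seed = 4)
  folds <- makeFolds(stageLabels(se), k = 5, seed = 1)
  cv <- crossValidate(se, 1:4, C = 1, gamma = 0.1, folds)
  expect_identical(cv$acc, 1)
  expect_identical(cv$mcc, 1)
  expect_identical(cv$fitness, 100)
  ct <- cv$counts
  expect_identical(ct$TP + ct$TN + ct$FP + ct$FN, ncol(se))
  expect_length(cv$foldAccuracies, 5L)
})

test_that("ROC/AUC follows the Mann-Whitney convention including ties", {
  perfect <- rocAuc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_identical(perfect$auc, 1)
  flat <- rocAuc(rep(2, 10), rep(c(0, 1), 5))
  expect_identical(flat$auc, 0.5)
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")

  bruteU <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(7)
  for (i in 1:30) {
    n <- sample(10:80, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq_len(8), n, replace = TRUE) + 0  # heavy ties
    r <- rocAuc(s, y)
    expect_equal(r$auc, bruteU(s, y), tolerance = 1e-12)
    expect_identical(r$points$fpr[1], 0)
    expect_identical(r$points$tpr[nrow(r$points)], 1)
    if (requireNamespace("pROC", quietly = TRUE)) {
      pr <- suppressMessages(pROC::auc(y, s, direction = "<"))
      expect_equal(r$auc, as.numeric(pr), tolerance = 1e-12)
    }
  }
})

test_that("jackknife equals n-fold cross-validation", {
  se <- makeSeparable(nPerClass = 12, seed = 6)
  expect_identical(jackknifeAccuracy(se, 1:4, C = 1, gamma = 0.1), 1)

  se2 <- makeCohort(nFeatures = 8, nPerClass = 15, nPlanted = 2,
                    shift = 1.2, seed = 8)
  n <- ncol(se2)
  jk <- jackknifeAccuracy(se2, 1:8, C = 1, gamma = 0.1)
  expect_true(jk >= 0 && jk <= 1)
  expect_identical(jk * n, round(jk * n))  # (#correct)/n
  loofolds <- structure(list(k = n, fold = seq_len(n), seed = 0L),
                        class = "foldAssignment")
  cvLoo <- suppressWarnings(
    crossValidate(se2, 1:8, C = 1, gamma = 0.1, loofolds))
  expect_equal(jk, cvLoo$acc, tolerance = 1e-12)
})
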