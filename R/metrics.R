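#' Confusion counts for binary stage predictions
#'
#' Tallies TP/TN/FP/FN with \emph{advanced} (code 1) as the positive class.
#'
#' @param yTrue,yPred equal-length vectors of 0/1 codes or
#'   \code{early}/\code{advanced} factors.
#' @return a named list of class \code{confusionCounts} with integer
#'   \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @export
confusionCounts <- function(yTrue, yPred) {
  yt <- as.integer(asStageFactor(yTrue) == "advanced")
  yp <- as.integer(asStageFactor(yPred) == "advanced")
  if (length(yt) != length(yp))
    stop("length mismatch: ", length(yt), " true vs ", length(yp),
         " predicted")
  structure(list(TP = sum(yt == 1L & yp == 1L),
                 TN = sum(yt == 0L & yp == 0L),
                 FP = sum(yt == 0L & yp == 1L),
                 FN = sum(yt == 1L & yp == 0L)),
            class = "confusionCounts")
}

#' Accuracy, sensitivity, specificity and MCC from confusion counts
#'
#' \deqn{ACC = (TP+TN)/N,\quad Sn = TP/(TP+FN),\quad Sp = TN/(TN+FP)}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' A zero denominator yields MCC = 0 (standard convention) and \code{NA}
#' (undefined) for Sn/Sp.
#'
#' @param counts a \code{\link{confusionCounts}} or a list/vector with
#'   elements \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @return named list: \code{acc}, \code{sn}, \code{sp}, \code{mcc}.
#' @export
classMetrics <- function(counts) {
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated samples")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(acc = (tp + tn) / total,
       sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       mcc = if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct score values (higher score
#' = more advanced-like), accumulating tied scores as a group, and integrates
#' the resulting ROC polygon by the trapezoidal rule. With this tie
#' convention the AUC equals the normalized Mann-Whitney U statistic
#' (ties counted 1/2).
#'
#' @param scores real-valued decision scores, one per sample.
#' @param labels 0/1 codes or \code{early}/\code{advanced}; both classes must
#'   be present.
#' @return list with \code{auc} and \code{points}, a data.frame of
#'   (\code{fpr}, \code{tpr}) vertices from (0,0) to (1,1).
#' @export
rocAuc <- function(scores, labels) {
  y <- as.integer(asStageFactor(labels) == "advanced")
  if (length(scores) != length(y)) stop("length mismatch")
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to build a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # group tied scores so the curve moves diagonally through ties
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tpCum <- cumsum(yy); fpCum <- cumsum(1L - yy)
  last <- which(c(diff(grp) != 0, TRUE))
  tpr <- c(0, tpCum[last] / nPos)
  fpr <- c(0, fpCum[last] / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  list(auc = auc, points = data.frame(fpr = fpr, tpr = tpr))
}

#' Write ROC curve points to CSV
#' @param roc result of \code{\link{rocAuc}}.
#' @param path output path (2-column CSV: fpr, tpr).
#' @export
writeRocPoints <- function(roc, path) {
  utils::write.table(roc$points, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
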