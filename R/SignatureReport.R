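#' SignatureReport: a selected signature with its supporting analyses
#'
#' Bundles a selected feature set with its MED (main effect difference)
#' scores, single-feature knockout accuracy differences, per-group expression
#' statistics, the SVM parameters of the selected model and its
#' cross-validation metrics. Features are kept ordered by descending MED
#' score, ties broken lexicographically by feature ID.
#'
#' @slot features ordered character vector of selected feature IDs.
#' @slot medScores numeric, named by feature (may be empty before ranking).
#' @slot knockoutDiffs numeric accuracy differences in percentage points,
#'   named by feature.
#' @slot groupStats data.frame with columns \code{feature}, \code{mean_early},
#'   \code{sd_early}, \code{mean_adv}, \code{sd_adv} (+ \code{scale} attr).
#' @slot svmParams named numeric of length 2: \code{C}, \code{gamma}.
#' @slot metrics list: the \code{CVResult} of the selected model.
#' @slot metadata list of free-form provenance (normalization method, seeds).
#'
#' @exportClass SignatureReport
setClass("SignatureReport",
         representation(features = "character",
                        medScores = "numeric",
                        knockoutDiffs = "numeric",
                        groupStats = "data.frame",
                        svmParams = "numeric",
                        metrics = "list",
                        metadata = "list"))

setValidity("SignatureReport", function(object) {
  msg <- character(0)
  if (length(object@features) == 0L)
    msg <- c(msg, "signature must be non-empty")
  if (anyDuplicated(object@features))
    msg <- c(msg, "duplicated features in signature")
  if (length(object@medScores) &&
      !all(names(object@medScores) %in% object@features))
    msg <- c(msg, "medScores names must be a subset of features")
  if (length(object@medScores) == length(object@features)) {
    ord <- order(-object@medScores[object@features])
    s <- object@medScores[object@features]
    if (is.unsorted(-s))
      msg <- c(msg, "features must be ordered by descending MED score")
  }
  if (length(object@svmParams) &&
      !all(c("C", "gamma") %in% names(object@svmParams)))
    msg <- c(msg, "svmParams must be named C, gamma")
  if (length(msg)) msg else TRUE
})

#' Construct a SignatureReport
#'
#' @param features character vector of selected feature IDs (non-empty).
#' @param medScores optional numeric named by feature; when supplied for all
#'   features, the feature order is recomputed as descending MED score with
#'   lexicographic tie-break.
#' @param knockoutDiffs,groupStats,svmParams,metrics,metadata see the class
#'   documentation.
#' @return a \linkS4class{SignatureReport}.
#' @export
SignatureReport <- function(features, medScores = numeric(0),
                            knockoutDiffs = numeric(0),
                            groupStats = data.frame(),
                            svmParams = numeric(0), metrics = list(),
                            metadata = list()) {
  features <- as.character(features)
  if (length(medScores) == length(features) && length(features) > 0L) {
    s <- medScores[features]
    ord <- order(-s, features)
    features <- features[ord]
  }
  new("SignatureReport", features = features, medScores = medScores,
      knockoutDiffs = knockoutDiffs, groupStats = groupStats,
      svmParams = svmParams, metrics = metrics, metadata = metadata)
}

#' @describeIn SignatureReport the ordered feature IDs.
#' @param x a \code{SignatureReport}.
#' @export
signatureFeatures <- function(x) x@features

#' @describeIn SignatureReport MED scores named by feature.
#' @export
medScores <- function(x) x@medScores

#' @describeIn SignatureReport knockout accuracy differences (percentage
#'   points) named by feature.
#' @export
knockoutDiffs <- function(x) x@knockoutDiffs

#' @describeIn SignatureReport cross-validation metrics of the selected model.
#' @export
reportMetrics <- function(x) x@metrics

setMethod("show", "SignatureReport", function(object) {
  cat("SignatureReport with", length(object@features), "features\n")
  if (length(object@svmParams))
    cat("  SVM: C =", object@svmParams[["C"]],
        ", gamma =", object@svmParams[["gamma"]], "\n")
  if (length(object@metrics))
    cat(sprintf("  10-CV: acc = %.4f, MCC = %.4f, AUC = %.4f\n",
                object@metrics$acc, object@metrics$mcc,
                object@metrics$auc %||% NA_real_))
  n <- min(length(object@features), 10L)
  cat("  top features:",
      paste(object@features[seq_len(n)], collapse = ", "), "\n")
})

#' Write / read a signature report as JSON
#'
#' Scores are serialized at full precision so that IDs and numbers round-trip
#' exactly.
#'
#' @param report a \linkS4class{SignatureReport}.
#' @param path output (or input) JSON path.
#' @return \code{writeSignatureReport} returns \code{path} invisibly;
#'   \code{readSignatureReport} the reconstructed report;
#'   \code{loadSignature} just the ordered feature IDs.
#' @export
writeSignatureReport <- function(report, path) {
  stopifnot(is(report, "SignatureReport"))
  validObject(report)
  obj <- list(features = report@features,
              med_scores = as.list(report@medScores),
              knockout_diffs = as.list(report@knockoutDiffs),
              group_stats = report@groupStats,
              svm_params = as.list(report@svmParams),
              metrics = cvResultAsList(report@metrics),
              metadata = report@metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

cvResultAsList <- function(m) {
  if (!length(m)) return(list())
  keep <- intersect(c("counts", "acc", "sn", "sp", "mcc", "auc",
                      "foldAccuracies", "fitness"), names(m))
  m <- m[keep]
  if (!is.null(m$counts)) m$counts <- unclass(m$counts)
  m
}

#' @rdname writeSignatureReport
#' @export
readSignatureReport <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("invalid JSON in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(obj$features) || length(obj$features) == 0L)
    stop("no features in report ", path)
  gs <- if (is.null(obj$group_stats) || length(obj$group_stats) == 0L)
    data.frame() else as.data.frame(obj$group_stats)
  SignatureReport(features = as.character(obj$features),
                  medScores = unlist(obj$med_scores) %||% numeric(0),
                  knockoutDiffs = unlist(obj$knockout_diffs) %||% numeric(0),
                  groupStats = gs,
                  svmParams = unlist(obj$svm_params) %||% numeric(0),
                  metrics = as.list(obj$metrics) %||% list(),
                  metadata = as.list(obj$metadata) %||% list())
}

#' @rdname writeSignatureReport
#' @export
loadSignature <- function(path) readSignatureReport(path)@features
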