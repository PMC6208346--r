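#' StageExperiment: a two-class expression experiment
#'
#' An S4 container for a feature-by-sample expression matrix together with a
#' binary tumour-stage label (\code{early} vs \code{advanced}) per sample.
#' It extends \linkS4class{SummarizedExperiment}: the first assay
#' (\code{"exprs"}) holds the working (possibly normalized) expression values;
#' when \code{\link{normalizeExpression}} has been applied, the original
#' values are retained in an assay named \code{"raw"} so that group statistics
#' can be reported on the pre-normalization scale.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}; the stage
#'   label lives in \code{colData(x)$stage} as a factor with levels
#'   \code{early}, \code{advanced}.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass StageExperiment
setClass("StageExperiment", contains = "SummarizedExperiment")

setValidity("StageExperiment", function(object) {
  msg <- character(0)
  if (!"stage" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'stage' column")
  else {
    st <- SummarizedExperiment::colData(object)$stage
    if (!is.factor(st) || !identical(levels(st), stageLevels))
      msg <- c(msg, "'stage' must be a factor with levels early, advanced")
  }
  if (length(SummarizedExperiment::assays(object)) < 1L)
    msg <- c(msg, "at least one assay required")
  else {
    a <- SummarizedExperiment::assay(object)
    if (anyNA(a)) msg <- c(msg, "expression values contain missing entries")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated feature IDs")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample IDs")
  if (length(msg)) msg else TRUE
})

#' Construct a StageExperiment
#'
#' Assembles an expression matrix (features x samples) and per-sample stage
#' labels into a validated \linkS4class{StageExperiment}. Samples are aligned
#' on the intersection of matrix column names and label names (matrix order
#' wins); an error is raised if the intersection is empty. Missing values are
#' rejected unless \code{impute = TRUE}, in which case each feature's missing
#' entries are replaced by that feature's median. A warning is emitted for
#' unbalanced classes.
#'
#' @param exprs numeric matrix, features in rows, samples in columns, with
#'   unique row and column names.
#' @param stage per-sample labels: a factor/character with values
#'   \code{early}/\code{advanced}, or 0/1 (1 = advanced). Either unnamed and
#'   parallel to the matrix columns, or named by sample ID.
#' @param impute replace missing values by the per-feature median instead of
#'   failing (default \code{FALSE}).
#' @return A \linkS4class{StageExperiment}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("mir", 1:3), paste0("s", 1:4)))
#' se <- StageExperiment(m, c("early", "early", "advanced", "advanced"))
#' stageLabels(se)
#' @export
StageExperiment <- function(exprs, stage, impute = FALSE) {
  if (!is.matrix(exprs)) exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("expression matrix must have feature and sample names")
  if (anyDuplicated(rownames(exprs)))
    stop("duplicated feature ID(s): ",
         paste(unique(rownames(exprs)[duplicated(rownames(exprs))]),
               collapse = ", "))
  if (anyDuplicated(colnames(exprs)))
    stop("duplicated sample ID(s): ",
         paste(unique(colnames(exprs)[duplicated(colnames(exprs))]),
               collapse = ", "))
  if (!is.null(names(stage))) {
    shared <- intersect(colnames(exprs), names(stage))
    if (length(shared) == 0L)
      stop("no samples shared between expression matrix and labels")
    exprs <- exprs[, shared, drop = FALSE]
    stage <- stage[shared]
  } else if (length(stage) != ncol(exprs)) {
    stop("labels (", length(stage), ") do not match samples (",
         ncol(exprs), ")")
  }
  stage <- asStageFactor(stage)
  if (nlevels(droplevels(stage)) < 2L)
    stop("both classes (early, advanced) must be present")
  if (anyNA(exprs)) {
    if (!impute)
      stop("expression matrix contains missing values (set impute = TRUE ",
           "to fill with per-feature medians)")
    for (i in which(rowSums(is.na(exprs)) > 0L)) {
      v <- exprs[i, ]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      exprs[i, ] <- v
    }
  }
  tab <- table(stage)
  if (tab["early"] != tab["advanced"])
    warning("unbalanced classes: ", tab["early"], " early vs ",
            tab["advanced"], " advanced")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(stage = stage, row.names = colnames(exprs)))
  new("StageExperiment", se)
}

#' @describeIn StageExperiment stage labels as a factor (early, advanced).
#' @param x a \code{StageExperiment}.
#' @export
stageLabels <- function(x) {
  stopifnot(is(x, "StageExperiment"))
  SummarizedExperiment::colData(x)$stage
}

#' @describeIn StageExperiment stage labels as 0/1 codes (1 = advanced,
#'   the positive class).
#' @export
stageCodes <- function(x) as.integer(stageLabels(x) == "advanced")

#' @describeIn StageExperiment the working expression matrix
#'   (features x samples).
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn StageExperiment the pre-normalization matrix when recorded,
#'   else the working matrix; the scale used is given in
#'   \code{attr(, "scale")}.
#' @export
rawValues <- function(x) {
  if ("raw" %in% SummarizedExperiment::assayNames(x)) {
    out <- SummarizedExperiment::assay(x, "raw")
    attr(out, "scale") <- "raw"
  } else {
    out <- SummarizedExperiment::assay(x, "exprs")
    attr(out, "scale") <- S4Vectors::metadata(x)$normalization %||% "stored"
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "StageExperiment", function(object) {
  cat("StageExperiment:", nrow(object), "features x", ncol(object),
      "samples\n")
  tab <- table(stageLabels(object))
  cat("  stages: early =", tab["early"], ", advanced =", tab["advanced"], "\n")
  nrm <- S4Vectors::metadata(object)$normalization
  if (!is.null(nrm)) cat("  normalization:", nrm, "\n")
  pl <- S4Vectors::metadata(object)$planted
  if (!is.null(pl)) cat("  planted features:", length(pl), "\n")
})
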