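#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV expression table with one header row and the feature (or
#' sample) IDs in the first column, and returns a numeric matrix oriented
#' features-by-samples regardless of the orientation on disk. IDs are
#' preserved verbatim.
#'
#' @param path path to a delimited text file. The delimiter is taken from the
#'   extension (\code{.csv} = comma, otherwise tab) unless \code{sep} is given.
#' @param orientation how the file is laid out: \code{"features-by-samples"}
#'   (default; rows are features) or \code{"samples-by-features"} (rows are
#'   samples; the matrix is transposed on load).
#' @param sep optional field separator overriding the extension heuristic.
#' @return numeric matrix, features in rows, samples in columns.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("features-by-samples",
                                                 "samples-by-features"),
                                 sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an ID column plus at least one value ",
                          "column in ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("non-numeric value '", v[bad[1L]], "' at row '", ids[bad[1L]],
             "', column '", colnames(body)[j], "' in ", path)
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (anyNA(m)) stop("missing values in ", path)
  if (orientation == "samples-by-features") m <- t(m)
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of \code{\link{readExpressionMatrix}}: writes a features-by-samples
#' matrix with an ID column named \code{feature}.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(m, path) {
  df <- data.frame(feature = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample stage labels
#'
#' Reads a two-column delimited file (sample ID, class token) and maps tokens
#' to the \code{early}/\code{advanced} factor. Tokens other than the defaults
#' can be accepted through \code{aliases}, e.g. pathological stage groups
#' \code{c(I = "early", II = "early", III = "advanced", IV = "advanced")}.
#'
#' @param path path to a two-column TSV/CSV (no header by default).
#' @param aliases named character vector mapping file tokens to
#'   \code{"early"}/\code{"advanced"}; unlisted tokens equal to a class name
#'   are accepted as-is.
#' @param header whether the file has a header row (default \code{FALSE}).
#' @return a factor with levels \code{early}, \code{advanced}, named by
#'   sample ID, in file order.
#' @export
readStageLabels <- function(path, aliases = NULL, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two columns (sample ID, class) in ", path)
  ids <- as.character(df[[1L]])
  tok <- as.character(df[[2L]])
  if (anyDuplicated(ids))
    stop("duplicated sample ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cls <- ifelse(tok %in% names(aliases), unname(aliases[tok]), tok)
  bad <- !cls %in% stageLevels
  if (any(bad))
    stop("unknown class token(s) in ", path, ": ",
         paste(unique(tok[bad]), collapse = ", "))
  stats::setNames(factor(cls, levels = stageLevels), ids)
}

#' Write per-sample stage labels to TSV
#' @param labels factor named by sample ID (see \code{\link{readStageLabels}}).
#' @param path output path.
#' @export
writeStageLabels <- function(labels, path) {
  utils::write.table(
    data.frame(sample = names(labels), stage = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize an expression matrix per feature
#'
#' \code{log2p1_zscore} (the default for counts-like input) applies
#' \eqn{x \to \log_2(x+1)} and then standardizes each feature to mean 0 and
#' unit SD (denominator \eqn{n}, the standard-scaler convention) across
#' samples; \code{zscore} standardizes only (appropriate for values already
#' on a log-like scale, e.g. simulated cohorts); \code{none}
#' leaves values untouched. Constant features are mapped to all-zeros rather
#' than dividing by zero. The original values are kept in the \code{"raw"}
#' assay and the method is recorded in \code{metadata(x)$normalization}.
#'
#' @param x a \linkS4class{StageExperiment} or a numeric matrix
#'   (features x samples).
#' @param method one of \code{"log2p1_zscore"}, \code{"zscore"},
#'   \code{"none"}.
#' @return an object of the same class as \code{x} with normalized values.
#' @export
normalizeExpression <- function(x, method = c("log2p1_zscore", "zscore",
                                              "none")) {
  method <- match.arg(method)
  m <- if (is(x, "StageExperiment")) exprValues(x) else x
  if (method == "none") {
    out <- m
  } else {
    if (method == "log2p1_zscore") {
      if (any(m < 0))
        stop("negative expression values are incompatible with log2(x+1)")
      m <- log2(m + 1)
    }
    mu <- rowMeans(m)
    s <- sqrt(rowMeans((m - mu)^2))   # population SD (denominator n)
    out <- (m - mu) / ifelse(s > 0, s, 1)
    out[s == 0, ] <- 0
  }
  if (is(x, "StageExperiment")) {
    if (method != "none") {
      raw <- if ("raw" %in% SummarizedExperiment::assayNames(x))
        SummarizedExperiment::assay(x, "raw") else exprValues(x)
      SummarizedExperiment::assays(x) <- list(exprs = out, raw = raw)
    }
    S4Vectors::metadata(x)$normalization <- method
    validObject(x)
    x
  } else out
}
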