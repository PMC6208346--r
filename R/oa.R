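#' Two-level orthogonal array
#'
#' Builds the first \code{nFactors} non-constant columns of the
#' Sylvester-Hadamard design \eqn{L_\beta(2^{\beta-1})} with
#' \eqn{\beta = 2^{\lceil \log_2(nFactors+1) \rceil}} rows. Every pair of
#' columns contains each of the level pairs (0,0), (0,1), (1,0), (1,1)
#' exactly \eqn{\beta/4} times — the balance property used both by the GA's
#' orthogonal-array crossover and by main-effect-difference ranking.
#'
#' @param nFactors number of 2-level factors (>= 2).
#' @return list of class \code{orthogonalArray}: \code{rows} (\eqn{\beta}),
#'   \code{cols} (\code{nFactors}) and \code{array}, a \code{rows x cols}
#'   0/1 integer matrix.
#' @examples
#' buildOA(3)$array   # the L4(2^3) design
#' @export
buildOA <- function(nFactors) {
  nFactors <- as.integer(nFactors)
  if (nFactors < 2L) stop("need at least 2 factors")
  beta <- as.integer(2^ceiling(log2(nFactors + 1)))
  H <- matrix(1, 1L, 1L)
  while (nrow(H) < beta) H <- rbind(cbind(H, H), cbind(H, -H))
  oa <- (1L - H[, 2L:(nFactors + 1L), drop = FALSE]) %/% 2L
  storage.mode(oa) <- "integer"
  structure(list(rows = beta, cols = nFactors, array = oa),
            class = "orthogonalArray")
}

#' @export
print.orthogonalArray <- function(x, ...) {
  cat("orthogonalArray: L", x$rows, "(2^", x$cols, ") — ", x$rows,
      " runs x ", x$cols, " factors\n", sep = "")
  invisible(x)
}
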