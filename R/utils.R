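#' @importFrom methods new is validObject setValidity slot
#' @importFrom stats predict rnorm runif sd cor
#' @importFrom utils read.delim write.table head
NULL

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
withLocalSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage seed from a global seed; keeps results < 2^31.
deriveSeed <- function(seed, offset) {
  (as.integer(seed) + 97L * as.integer(offset)) %% 2147483629L
}

stageLevels <- c("early", "advanced")

asStageFactor <- function(x) {
  if (is.factor(x)) {
    if (!all(levels(x) %in% stageLevels))
      stop("stage labels must use levels 'early'/'advanced'")
    factor(as.character(x), levels = stageLevels)
  } else if (is.numeric(x)) {
    if (!all(x %in% c(0, 1)))
      stop("numeric stage labels must be 0 (early) or 1 (advanced)")
    factor(stageLevels[x + 1L], levels = stageLevels)
  } else {
    if (!all(x %in% stageLevels))
      stop("unknown stage token(s): ",
           paste(unique(setdiff(x, stageLevels)), collapse = ", "))
    factor(x, levels = stageLevels)
  }
}
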