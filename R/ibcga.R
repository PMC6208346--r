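#' IBCGA configuration
#'
#' The inheritable bi-objective combinatorial GA evolves feature subsets of
#' fixed cardinality \code{r}, sweeping \code{r} from \code{rStart} to
#' \code{rEnd}: at the end of each phase every individual inherits its genes
#' plus one extra randomly activated feature. Each chromosome carries
#' \code{n} binary feature genes and two 4-bit genes encoding the SVM
#' parameters on the grids \eqn{C = 2^{c-5}} (\eqn{2^{-5}..2^{10}}) and
#' \eqn{\gamma = 2^{g-15}} (\eqn{2^{-15}..2^{0}}).
#'
#' @param rStart,rEnd smallest and largest signature cardinality
#'   (defaults 10 and 50).
#' @param nPop population size (even; default 50).
#' @param gMax generation budget (default 60). With
#'   \code{gMaxMode = "total"} (default) it is the total number of
#'   generations, split as evenly as possible across the
#'   \code{rEnd - rStart + 1} phases; with \code{"per-phase"} every phase
#'   runs \code{gMax} generations.
#' @param tournamentSize tournament size for selection (default 2).
#' @param crossoverRate probability a mating-pool pair undergoes
#'   orthogonal-array crossover rather than being copied (default 0.8).
#' @param mutationFraction fraction of non-elite individuals mutated per
#'   generation (default 0.2).
#' @param paramMutationRate probability each 4-bit parameter gene is
#'   re-randomized during mutation (default 0.1).
#' @param paramStepRate probability each 4-bit parameter gene takes a
#'   \eqn{\pm 1} creep step during mutation (default 0.3).
#' @param gammaSegments number of contiguous chromosome segments (factors)
#'   used by the orthogonal-array crossover (default 7, giving an 8-run
#'   array).
#' @param patience stop a phase early after this many generations without
#'   elite improvement (default \code{Inf} = never).
#' @param seed master seed for all GA randomness.
#' @param runs number of independent runs for \code{\link{repeatedRuns}}.
#' @param k cross-validation fold count for the default SVM fitness.
#' @return list of class \code{ibcgaConfig}.
#' @export
ibcgaConfig <- function(rStart = 10L, rEnd = 50L, nPop = 50L, gMax = 60L,
                        tournamentSize = 2L, crossoverRate = 0.8,
                        mutationFraction = 0.2, paramMutationRate = 0.1,
                        paramStepRate = 0.3, gammaSegments = 7L,
                        gMaxMode = c("total", "per-phase"),
                        patience = Inf, seed = 1L, runs = 1L, k = 10L) {
  gMaxMode <- match.arg(gMaxMode)
  if (rStart > rEnd) stop("rStart must be <= rEnd")
  if (nPop %% 2L != 0L) stop("nPop must be even")
  structure(list(rStart = as.integer(rStart), rEnd = as.integer(rEnd),
                 nPop = as.integer(nPop), gMax = as.integer(gMax),
                 tournamentSize = as.integer(tournamentSize),
                 crossoverRate = crossoverRate,
                 mutationFraction = mutationFraction,
                 paramMutationRate = paramMutationRate,
                 paramStepRate = paramStepRate,
                 gammaSegments = as.integer(gammaSegments),
                 gMaxMode = gMaxMode, patience = patience,
                 seed = as.integer(seed), runs = as.integer(runs),
                 k = as.integer(k)),
            class = "ibcgaConfig")
}

#' Construct a GA chromosome
#'
#' @param n number of feature genes.
#' @param features indices of active (1) feature genes.
#' @param cGene,gGene 4-bit integers in 0..15 encoding C and gamma.
#' @return list of class \code{gaChromosome}: logical \code{feat}, integers
#'   \code{c}, \code{g}, cached \code{fit} (or NULL).
#' @export
gaChromosome <- function(n, features = integer(0), cGene = 5L, gGene = 11L) {
  if (cGene < 0L || cGene > 15L || gGene < 0L || gGene > 15L)
    stop("parameter genes must lie in 0..15")
  feat <- logical(n)
  feat[features] <- TRUE
  structure(list(feat = feat, c = as.integer(cGene), g = as.integer(gGene),
                 fit = NULL),
            class = "gaChromosome")
}

chromKey <- function(ch) {
  paste0(ch$c, ".", ch$g, ":", paste(which(ch$feat), collapse = ","))
}

#' Decode a GA chromosome
#'
#' @param chrom a \code{\link{gaChromosome}}.
#' @return list: \code{features} (indices of 1-genes), \code{C}
#'   (\eqn{2^{c-5}}), \code{gamma} (\eqn{2^{g-15}}).
#' @export
decodeChromosome <- function(chrom) {
  list(features = which(chrom$feat), C = 2^(chrom$c - 5),
       gamma = 2^(chrom$g - 15))
}

#' Default SVM cross-validation fitness
#'
#' Wraps a \linkS4class{StageExperiment} and a fold assignment into the GA's
#' fitness function: pooled k-fold cross-validation accuracy in percent for
#' the decoded feature subset and (C, gamma). Chromosomes with an empty
#' subset score 0.
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param folds a \code{\link{makeFolds}} assignment, fixed for the whole run
#'   so all chromosomes are compared on identical folds.
#' @return a function \code{chromosome -> fitness (0..100)}.
#' @export
svmFitness <- function(se, folds) {
  X <- t(exprValues(se))
  y <- stageLabels(se)
  force(folds)
  function(ch) {
    d <- decodeChromosome(ch)
    if (length(d$features) == 0L) return(0)
    res <- tryCatch(cvCore(X, y, d$features, d$C, d$gamma, folds),
                    error = function(e) NULL)
    if (is.null(res)) 0 else res$fitness
  }
}

makeEvaluator <- function(fitnessFn, useCache = TRUE) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  count <- 0L
  evalFn <- function(ch) {
    if (!any(ch$feat)) return(0)
    key <- chromKey(ch)
    if (useCache) {
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
    }
    count <<- count + 1L
    v <- fitnessFn(ch)
    if (useCache) cache[[key]] <- v
    v
  }
  list(eval = evalFn, count = function() count)
}

#' Random initial population
#'
#' @param config an \code{\link{ibcgaConfig}} (uses \code{nPop},
#'   \code{rStart}); call inside an already-seeded context or rely on
#'   \code{\link{runIBCGA}}'s seeding.
#' @param n number of feature genes.
#' @return list of \code{nPop} chromosomes, each with exactly \code{rStart}
#'   active feature genes at uniform random positions and uniform 4-bit
#'   parameter genes.
#' @export
initPopulation <- function(config, n) {
  if (config$rStart > n) stop("rStart exceeds number of features")
  lapply(seq_len(config$nPop), function(i)
    gaChromosome(n, sample.int(n, config$rStart),
                 sample(0:15, 1L), sample(0:15, 1L)))
}

#' Binary tournament selection
#'
#' Samples \code{size} individuals uniformly (with replacement across
#' tournaments, without within one) and returns the index of the fittest;
#' exact ties are resolved uniformly at random.
#'
#' @param fitness numeric fitness per individual.
#' @param size tournament size (default 2).
#' @return the selected individual's index.
#' @export
tournamentSelect <- function(fitness, size = 2L) {
  idx <- sample.int(length(fitness), size)
  best <- idx[fitness[idx] == max(fitness[idx])]
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  best
}

#' Repair a chromosome to exact cardinality r
#'
#' Randomly clears surplus 1-genes or sets missing ones so that exactly
#' \code{r} feature genes are active.
#'
#' @param chrom a \code{\link{gaChromosome}}.
#' @param r target cardinality (<= number of feature genes).
#' @return the repaired chromosome (fitness cache invalidated if changed).
#' @export
repairChromosome <- function(chrom, r) {
  n <- length(chrom$feat)
  if (r > n) stop("r exceeds number of feature genes")
  k <- sum(chrom$feat)
  if (k > r) {
    ones <- which(chrom$feat)
    chrom$feat[ones[sample.int(k, k - r)]] <- FALSE
    chrom$fit <- NULL
  } else if (k < r) {
    zeros <- which(!chrom$feat)
    chrom$feat[zeros[sample.int(length(zeros), r - k)]] <- TRUE
    chrom$fit <- NULL
  }
  chrom
}

#' Swap mutation with parameter-gene creep and re-randomization
#'
#' Exchanges one random active and one random inactive feature gene
#' (preserving cardinality; a no-op when all genes are active or inactive).
#' Each 4-bit parameter gene is re-randomized uniformly with probability
#' \code{paramRate} (exploration) or stepped by \eqn{\pm 1} (clipped to
#' 0..15) with probability \code{stepRate} — the standard creep mutation for
#' integer-coded genes, which lets elitist selection hill-climb the
#' parameter grids where neighbouring values have correlated fitness. The
#' fitness cache is invalidated.
#'
#' @param chrom a \code{\link{gaChromosome}}.
#' @param paramRate per-gene uniform re-randomization probability
#'   (default 0.1).
#' @param stepRate per-gene \eqn{\pm 1} creep probability (default 0.3).
#' @return the mutated chromosome.
#' @export
mutateChromosome <- function(chrom, paramRate = 0.1, stepRate = 0.3) {
  ones <- which(chrom$feat)
  zeros <- which(!chrom$feat)
  if (length(ones) > 0L && length(zeros) > 0L) {
    chrom$feat[ones[sample.int(length(ones), 1L)]] <- FALSE
    chrom$feat[zeros[sample.int(length(zeros), 1L)]] <- TRUE
  }
  mutGene <- function(v) {
    u <- stats::runif(1)
    if (u < paramRate) sample(0:15, 1L)
    else if (u < paramRate + stepRate)
      max(0L, min(15L, v + sample(c(-1L, 1L), 1L)))
    else v
  }
  chrom$c <- mutGene(chrom$c)
  chrom$g <- mutGene(chrom$g)
  chrom$fit <- NULL
  chrom
}

#' Orthogonal-array crossover
#'
#' Cuts both parents into \code{config$gammaSegments} contiguous segments
#' spanning the full chromosome (feature genes followed by the two parameter
#' genes). Each row of the 2-level orthogonal array assembles a candidate
#' taking segment \code{j} from parent 1 at level 0 and from parent 2 at
#' level 1; all candidates are repaired to cardinality \code{r} and
#' evaluated. Factor main effects (mean fitness per level) predict a best
#' candidate assembled from each factor's better level, which is also
#' evaluated. The two fittest distinct chromosomes among the candidates, the
#' predicted best and the two parents are returned — so offspring fitness
#' never falls below both parents'.
#'
#' @param p1,p2 parent chromosomes (already at cardinality \code{r}).
#' @param r cardinality to maintain.
#' @param evaluator a fitness closure \code{chromosome -> fitness}.
#' @param config an \code{\link{ibcgaConfig}} (uses \code{gammaSegments}).
#' @return list of two offspring chromosomes with \code{$fit} set.
#' @export
oaCrossover <- function(p1, p2, r, evaluator, config = ibcgaConfig()) {
  n <- length(p1$feat)
  segs <- config$gammaSegments
  oa <- buildOA(segs)$array
  cut <- unique(round(seq(0, n + 2, length.out = segs + 1)))
  segs <- length(cut) - 1L   # degenerate tiny n: fewer usable segments
  if (segs < 2L) return(orderedPair(p1, p2, evaluator))
  if (segs < ncol(oa)) oa <- buildOA(segs)$array
  segIdx <- lapply(seq_len(segs), function(j) (cut[j] + 1L):cut[j + 1L])

  assemble <- function(levels) {
    ch <- p1
    for (j in which(levels == 1L)) {
      pos <- segIdx[[j]]
      fpos <- pos[pos <= n]
      ch$feat[fpos] <- p2$feat[fpos]
      if ((n + 1L) %in% pos) ch$c <- p2$c
      if ((n + 2L) %in% pos) ch$g <- p2$g
    }
    ch$fit <- NULL
    repairChromosome(ch, r)
  }

  cand <- lapply(seq_len(nrow(oa)), function(i) assemble(oa[i, ]))
  fits <- vapply(cand, evaluator, numeric(1))
  for (i in seq_along(cand)) cand[[i]]$fit <- fits[i]
  # factor main effects and predicted-best assembly
  bestLevels <- vapply(seq_len(ncol(oa)), function(j) {
    s1 <- mean(fits[oa[, j] == 1L])
    s0 <- mean(fits[oa[, j] == 0L])
    if (s1 > s0) 1L else if (s1 < s0) 0L else
      sample(c(0L, 1L), 1L)
  }, integer(1))
  pred <- assemble(bestLevels)
  pred$fit <- evaluator(pred)
  if (is.null(p1$fit)) p1$fit <- evaluator(p1)
  if (is.null(p2$fit)) p2$fit <- evaluator(p2)
  pool <- c(cand, list(pred, p1, p2))
  keys <- vapply(pool, chromKey, character(1))
  keep <- !duplicated(keys)
  pool <- pool[keep]
  ord <- order(-vapply(pool, `[[`, numeric(1), "fit"))
  if (length(pool) == 1L) pool[c(1L, 1L)] else pool[ord[1:2]]
}

orderedPair <- function(p1, p2, evaluator) {
  if (is.null(p1$fit)) p1$fit <- evaluator(p1)
  if (is.null(p2$fit)) p2$fit <- evaluator(p2)
  list(p1, p2)
}

# one generation: tournament mating pool, OA crossover, elite-protected
# mutation, generational replacement with elite preservation
stepGeneration <- function(pop, r, evaluator, config) {
  nPop <- config$nPop
  fits <- vapply(pop, `[[`, numeric(1), "fit")
  elite <- pop[[which.max(fits)]]
  pool <- lapply(seq_len(nPop), function(i)
    pop[[tournamentSelect(fits, config$tournamentSize)]])
  newPop <- vector("list", nPop)
  for (i in seq(1L, nPop - 1L, by = 2L)) {
    off <- if (stats::runif(1) < config$crossoverRate)
      oaCrossover(pool[[i]], pool[[i + 1L]], r, evaluator, config)
    else orderedPair(pool[[i]], pool[[i + 1L]], evaluator)
    newPop[[i]] <- off[[1L]]
    newPop[[i + 1L]] <- off[[2L]]
  }
  # mutation, never applied to the current best individual
  newFits <- vapply(newPop, `[[`, numeric(1), "fit")
  protect <- which.max(newFits)
  candidates <- setdiff(seq_len(nPop), protect)
  nMut <- min(round(config$mutationFraction * nPop), length(candidates))
  if (nMut > 0L) {
    for (i in candidates[sample.int(length(candidates), nMut)]) {
      ch <- mutateChromosome(newPop[[i]], config$paramMutationRate,
                             config$paramStepRate)
      ch$fit <- evaluator(ch)
      newPop[[i]] <- ch
    }
  }
  # keep the elite alive across generations
  newFits <- vapply(newPop, `[[`, numeric(1), "fit")
  if (max(newFits) < elite$fit) newPop[[which.min(newFits)]] <- elite
  newPop
}

#' Run the inheritable bi-objective combinatorial GA
#'
#' Evolves fixed-cardinality feature subsets for each cardinality
#' \code{r = rStart..rEnd} (selection, orthogonal-array crossover,
#' elite-protected swap mutation, generational replacement with elitism),
#' then lets every individual inherit its genes plus one extra random
#' feature before moving to \code{r + 1}. The final solution is the per-phase
#' best with the highest fitness; ties go to the smaller cardinality
#' (the bi-objective preference for compact signatures). Fitness values are
#' memoized by (feature subset, C, gamma); the default fitness is pooled
#' k-fold CV accuracy of an RBF SVM (\code{\link{svmFitness}}).
#'
#' @param se a normalized labeled \linkS4class{StageExperiment}; may be
#'   \code{NULL} when \code{fitnessFn} and \code{nFeatures} are supplied.
#' @param config an \code{\link{ibcgaConfig}}.
#' @param fitnessFn optional custom fitness \code{chromosome -> fitness};
#'   must be deterministic (it is memoized).
#' @param nFeatures chromosome length when \code{se} is \code{NULL}.
#' @param folds optional \code{\link{makeFolds}} assignment for the default
#'   fitness (default: k from config, seed derived from config seed).
#' @param useCache memoize fitness evaluations (default TRUE; results are
#'   identical either way for a fixed seed).
#' @param diagnostics record per-generation population cardinality ranges
#'   (for invariant checking; default FALSE).
#' @return list of class \code{ibcgaResult}: \code{best} (features, C,
#'   gamma, fitness, r), \code{perPhase} data.frame, \code{trajectory}
#'   data.frame (generation, r, bestFitness, evaluations),
#'   \code{evaluations}, \code{folds}, \code{config}, and
#'   \code{diagnostics} when requested.
#' @export
runIBCGA <- function(se = NULL, config = ibcgaConfig(), fitnessFn = NULL,
                     nFeatures = NULL, folds = NULL, useCache = TRUE,
                     diagnostics = FALSE) {
  if (is.null(fitnessFn)) {
    stopifnot(is(se, "StageExperiment"))
    if (is.null(folds))
      folds <- makeFolds(stageLabels(se), k = config$k,
                         seed = deriveSeed(config$seed, 1L))
    fitnessFn <- svmFitness(se, folds)
  }
  n <- if (!is.null(nFeatures)) as.integer(nFeatures) else nrow(se)
  if (config$rEnd > n) stop("rEnd exceeds number of features")
  evaluator <- makeEvaluator(fitnessFn, useCache)
  ev <- evaluator$eval

  phases <- config$rStart:config$rEnd
  nPhase <- length(phases)
  gens <- if (config$gMaxMode == "per-phase") rep(config$gMax, nPhase)
  else {
    base <- config$gMax %/% nPhase
    extra <- config$gMax %% nPhase
    base + as.integer(seq_len(nPhase) <= extra)
  }

  traj <- list()
  diag <- list()
  perPhase <- vector("list", nPhase)
  genCounter <- 0L

  withLocalSeed(config$seed, {
    pop <- initPopulation(config, n)
    for (i in seq_along(pop)) pop[[i]]$fit <- ev(pop[[i]])
    for (p in seq_len(nPhase)) {
      r <- phases[p]
      sinceImprove <- 0L
      bestSoFar <- max(vapply(pop, `[[`, numeric(1), "fit"))
      g <- 0L
      while (g < gens[p] && sinceImprove < config$patience) {
        pop <- stepGeneration(pop, r, ev, config)
        g <- g + 1L
        genCounter <- genCounter + 1L
        fits <- vapply(pop, `[[`, numeric(1), "fit")
        if (max(fits) > bestSoFar) {
          bestSoFar <- max(fits)
          sinceImprove <- 0L
        } else sinceImprove <- sinceImprove + 1L
        traj[[length(traj) + 1L]] <-
          data.frame(generation = genCounter, r = r,
                     bestFitness = max(fits),
                     evaluations = evaluator$count())
        if (diagnostics) {
          pc <- vapply(pop, function(ch) sum(ch$feat), integer(1))
          diag[[length(diag) + 1L]] <-
            data.frame(generation = genCounter, r = r,
                       minCard = min(pc), maxCard = max(pc))
        }
      }
      fits <- vapply(pop, `[[`, numeric(1), "fit")
      bestIdx <- which.max(fits)
      perPhase[[p]] <- list(r = r, chrom = pop[[bestIdx]],
                            fitness = fits[bestIdx])
      if (r < config$rEnd) {
        # inheritance: every individual gains one random inactive feature
        for (i in seq_along(pop)) {
          zeros <- which(!pop[[i]]$feat)
          if (length(zeros) > 0L) {
            pop[[i]]$feat[zeros[sample.int(length(zeros), 1L)]] <- TRUE
            pop[[i]]$fit <- NULL
          }
          pop[[i]]$fit <- ev(pop[[i]])
        }
      }
    }
  })

  phaseFit <- vapply(perPhase, `[[`, numeric(1), "fitness")
  bestPhase <- which.max(phaseFit)   # first max -> smallest r on ties
  bestChrom <- perPhase[[bestPhase]]$chrom
  dec <- decodeChromosome(bestChrom)
  featNames <- if (!is.null(se)) rownames(se)[dec$features] else dec$features
  perPhaseDf <- data.frame(
    r = vapply(perPhase, `[[`, integer(1), "r"),
    fitness = phaseFit,
    C = vapply(perPhase, function(x) decodeChromosome(x$chrom)$C,
               numeric(1)),
    gamma = vapply(perPhase, function(x) decodeChromosome(x$chrom)$gamma,
                   numeric(1)))
  out <- list(best = list(features = featNames,
                          featureIdx = dec$features, C = dec$C,
                          gamma = dec$gamma,
                          fitness = phaseFit[bestPhase],
                          r = phases[bestPhase], chrom = bestChrom),
              perPhase = perPhaseDf,
              perPhaseChroms = lapply(perPhase, `[[`, "chrom"),
              trajectory = do.call(rbind, traj),
              evaluations = evaluator$count(),
              folds = if (is.null(se)) NULL else folds,
              config = config)
  if (diagnostics) out$diagnostics <- do.call(rbind, diag)
  class(out) <- "ibcgaResult"
  out
}

#' @export
print.ibcgaResult <- function(x, ...) {
  cat("ibcgaResult: best fitness", sprintf("%.2f%%", x$best$fitness),
      "at r =", x$best$r, "\n")
  cat("  C =", x$best$C, " gamma =", x$best$gamma, " evaluations =",
      x$evaluations, "\n")
  invisible(x)
}

#' Repeated independent IBCGA runs
#'
#' Runs the GA \code{config$runs} times with independent derived seeds and
#' summarizes the per-run best fitnesses (mean, SD, per-fold mean of the best
#' run) alongside the overall best signature; ties between runs go to the
#' smaller signature.
#'
#' @inheritParams runIBCGA
#' @return list of class \code{ibcgaRuns}: \code{runs} (list of
#'   \code{ibcgaResult}), \code{fitnesses}, \code{meanFitness},
#'   \code{sdFitness}, \code{best} (the winning run's best solution),
#'   \code{bestRun}.
#' @export
repeatedRuns <- function(se, config = ibcgaConfig(), folds = NULL, ...) {
  stopifnot(config$runs >= 1L)
  results <- vector("list", config$runs)
  for (i in seq_len(config$runs)) {
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, 1000L + i)
    results[[i]] <- runIBCGA(se, cfg, folds = folds, ...)
  }
  fits <- vapply(results, function(x) x$best$fitness, numeric(1))
  sizes <- vapply(results, function(x) x$best$r, numeric(1))
  bestRun <- order(-fits, sizes)[1L]
  structure(list(runs = results, fitnesses = fits,
                 meanFitness = mean(fits),
                 sdFitness = if (length(fits) > 1L) stats::sd(fits) else 0,
                 best = results[[bestRun]]$best, bestRun = bestRun,
                 config = config),
            class = "ibcgaRuns")
}

#' @export
print.ibcgaRuns <- function(x, ...) {
  cat(sprintf("ibcgaRuns: %d run(s), fitness %.2f%% +/- %.2f%% (best %.2f%%)\n",
              length(x$runs), x$meanFitness, x$sdFitness,
              max(x$fitnesses)))
  invisible(x)
}
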