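# A cheap deterministic fitness used throughout: additive feature weights
# plus a small parameter bonus. Lets GA mechanics be tested without an SVM.
toyFitness <- function(weights, paramBonus = 0) {
  function(ch) {
    sum(weights[ch$feat]) + paramBonus * (ch$c + ch$g) / 30
  }
}

test_that("chromosomes decode onto the standard libsvm parameter grids", {
  ch <- gaChromosome(10, c(2, 5), cGene = 5, gGene = 15)
  d <- decodeChromosome(ch)
  expect_identical(d$features, c(2L, 5L))
  expect_identical(d$C, 1)
  expect_identical(d$gamma, 1)
  expect_identical(decodeChromosome(gaChromosome(4, 1, 0, 0))$C, 2^-5)
  expect_identical(decodeChromosome(gaChromosome(4, 1, 15, 0))$C, 2^10)
  expect_identical(decodeChromosome(gaChromosome(4, 1, 0, 0))$gamma, 2^-15)
  expect_error(gaChromosome(4, 1, cGene = 16), "0..15")
  d0 <- decodeChromosome(gaChromosome(6))
  expect_length(d0$features, 0L)
})

test_that("orthogonal arrays are pairwise balanced for all supported sizes", {
  expect_identical(buildOA(3)$rows, 4L)
  expect_identical(buildOA(7)$rows, 8L)
  for (g in 2:31) {
    oa <- buildOA(g)
    beta <- oa$rows
    expect_identical(beta, as.integer(2^ceiling(log2(g + 1))))
    a <- oa$array
    expect_true(all(a %in% 0:1))
    for (i in seq_len(g - 1)) for (j in (i + 1):g) {
      tab <- table(factor(a[, i], 0:1), factor(a[, j], 0:1))
      expect_true(all(tab == beta / 4))
    }
  }
})

test_that("initial populations have exact cardinality and seeded determinism", {
  cfg <- ibcgaConfig(rStart = 7, rEnd = 12, nPop = 20, seed = 5)
  set.seed(5)
  pop <- initPopulation(cfg, 50)
  expect_length(pop, 20L)
  expect_true(all(vapply(pop, function(ch) sum(ch$feat), 0L) == 7L))
  expect_true(all(vapply(pop, `[[`, 0L, "c") %in% 0:15))
  set.seed(5)
  pop2 <- initPopulation(cfg, 50)
  expect_identical(pop, pop2)
  # positions roughly uniform across features
  set.seed(1)
  counts <- integer(50)
  for (i in 1:500) {
    ch <- initPopulation(ibcgaConfig(rStart = 5, rEnd = 5, nPop = 2), 50)[[1]]
    counts[ch$feat] <- counts[ch$feat] + 1L
  }
  expect_gt(suppressWarnings(
    chisq.test(counts, p = rep(1 / 50, 50))$p.value), 0.001)
})

test_that("tournament selection prefers the fitter and is fair under ties", {
  set.seed(2)
  fits <- c(90, 10)
  picks <- replicate(200, tournamentSelect(fits))
  # whenever both are drawn the fitter wins; 1 never loses a tournament
  expect_true(all(picks %in% c(1L, 2L)))
  expect_gt(mean(picks == 1L), 0.6)
  # selection pressure: mean fitness of a mating pool >= population mean
  popFits <- runif(30, 0, 100)
  pools <- replicate(500, popFits[tournamentSelect(popFits)])
  expect_gt(mean(pools), mean(popFits))
  # equal fitness -> uniform choice
  eq <- replicate(3000, tournamentSelect(rep(5, 4)))
  expect_gt(suppressWarnings(
    chisq.test(tabulate(eq, 4), p = rep(0.25, 4))$p.value), 0.001)
})

test_that("repair enforces exact cardinality uniformly at random", {
  set.seed(3)
  ch <- gaChromosome(20, 1:5)
  expect_identical(repairChromosome(ch, 5), ch)
  over <- gaChromosome(20, 1:9)
  expect_identical(sum(repairChromosome(over, 5)$feat), 5L)
  under <- gaChromosome(20)
  expect_identical(sum(repairChromosome(under, 5)$feat), 5L)
  expect_error(repairChromosome(ch, 21), "exceeds")
  # which bits get added is uniform over the zero positions
  counts <- integer(20)
  for (i in 1:2000) {
    r <- repairChromosome(gaChromosome(20, 1:10), 11)
    counts <- counts + (r$feat & !gaChromosome(20, 1:10)$feat)
  }
  expect_gt(suppressWarnings(
    chisq.test(counts[11:20], p = rep(0.1, 10))$p.value), 0.001)
})

test_that("swap mutation conserves cardinality and explores all features", {
  set.seed(4)
  ch <- gaChromosome(50, sample(50, 8))
  for (i in 1:50) {
    m <- mutateChromosome(ch)
    expect_identical(sum(m$feat), 8L)
    expect_null(m$fit)
  }
  # r = n leaves feature genes untouched
  full <- gaChromosome(6, 1:6)
  expect_identical(mutateChromosome(full)$feat, full$feat)
  # repeated mutation reaches every feature index
  seen <- rep(FALSE, 50)
  cur <- gaChromosome(50, 1:8)
  for (i in 1:3000) {
    cur <- mutateChromosome(cur)
    seen <- seen | cur$feat
  }
  expect_true(all(seen))
})

test_that("OA crossover returns the fittest distinct pool members", {
  set.seed(6)
  w <- runif(20)
  ev <- toyFitness(w)
  cfg <- ibcgaConfig(rStart = 5, rEnd = 5, nPop = 10)
  p1 <- gaChromosome(20, 1:5); p1$fit <- ev(p1)
  p2 <- gaChromosome(20, 1:5); p2$fit <- ev(p2)
  # identical parents: offspring identical to them
  off <- oaCrossover(p1, p2, r = 5, evaluator = ev, config = cfg)
  expect_identical(off[[1]]$feat, p1$feat)
  expect_identical(off[[2]]$feat, p1$feat)
  # offspring never fall below both parents (parents are in the pool)
  for (i in 1:20) {
    a <- gaChromosome(20, sample(20, 5)); a$fit <- ev(a)
    b <- gaChromosome(20, sample(20, 5)); b$fit <- ev(b)
    off <- oaCrossover(a, b, r = 5, evaluator = ev, config = cfg)
    expect_gte(off[[1]]$fit, min(a$fit, b$fit))
    expect_gte(off[[2]]$fit, min(a$fit, b$fit))
    expect_identical(sum(off[[1]]$feat), 5L)
    expect_identical(sum(off[[2]]$feat), 5L)
  }
})

test_that("main-effect prediction recovers the best segment combination", {
  # Parents are segment-aligned (equal per-segment cardinality) so no repair
  # randomness: an additive fitness makes the exhaustive 2^segments optimum
  # well-defined; the OA pool should usually contain it.
  set.seed(8)
  segs <- 5L
  n <- 20L  # n + 2 = 22 positions; ~4-5 per segment
  cfg <- ibcgaConfig(rStart = 5, rEnd = 5, nPop = 10, gammaSegments = segs)
  cut <- unique(round(seq(0, n + 2, length.out = segs + 1)))
  hits <- 0L
  trials <- 100L
  for (t in seq_len(trials)) {
    w <- runif(n, -1, 1)
    ev <- toyFitness(w)
    feats1 <- feats2 <- logical(n)
    for (j in seq_len(segs)) {
      pos <- (cut[j] + 1):cut[j + 1]
      pos <- pos[pos <= n]
      if (length(pos) >= 2) {
        pick <- sample(pos, 2)
        feats1[pick[1]] <- TRUE
        feats2[pick[2]] <- TRUE
      }
    }
    p1 <- gaChromosome(n, which(feats1)); p1$fit <- ev(p1)
    p2 <- gaChromosome(n, which(feats2)); p2$fit <- ev(p2)
    r <- sum(feats1)
    # exhaustive oracle over all 2^segs segment selections
    bestFit <- -Inf
    for (mask in 0:(2^segs - 1)) {
      lv <- as.integer(intToBits(mask))[seq_len(segs)]
      ch <- p1
      for (j in which(lv == 1L)) {
        pos <- (cut[j] + 1):cut[j + 1]
        fpos <- pos[pos <= n]
        ch$feat[fpos] <- p2$feat[fpos]
      }
      bestFit <- max(bestFit, ev(ch))
    }
    off <- oaCrossover(p1, p2, r = r, evaluator = ev, config = cfg)
    if (off[[1]]$fit >= bestFit - 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 80L)
})

test_that("the GA conserves cardinality, elitism and inheritance structure", {
  set.seed(9)
  w <- runif(40)
  cfg <- ibcgaConfig(rStart = 4, rEnd = 8, nPop = 10, gMax = 10,
                     gMaxMode = "total", seed = 11)
  res <- runIBCGA(config = cfg, fitnessFn = toyFitness(w, paramBonus = 0.1),
                  nFeatures = 40, diagnostics = TRUE)
  # cardinality r conserved in every generation of each phase
  expect_true(all(res$diagnostics$minCard == res$diagnostics$r))
  expect_true(all(res$diagnostics$maxCard == res$diagnostics$r))
  # elite fitness non-decreasing within each phase
  for (r in unique(res$trajectory$r)) {
    tr <- res$trajectory$bestFitness[res$trajectory$r == r]
    expect_true(all(diff(tr) >= 0))
  }
  # per-phase bests recorded for every r, sizes match the phase
  expect_identical(res$perPhase$r, 4:8)
  sizes <- vapply(res$perPhaseChroms, function(ch) sum(ch$feat), 0L)
  expect_identical(sizes, 4:8)
  # final signature size within [rStart, rEnd]
  expect_true(res$best$r >= 4 && res$best$r <= 8)
  expect_identical(length(res$best$featureIdx), res$best$r)
  # overall best = max over per-phase bests
  expect_identical(res$best$fitness, max(res$perPhase$fitness))
})

test_that("memoization does not change the trajectory", {
  w <- runif(30)
  cfg <- ibcgaConfig(rStart = 3, rEnd = 6, nPop = 10, gMax = 8, seed = 21)
  a <- runIBCGA(config = cfg, fitnessFn = toyFitness(w, 0.2),
                nFeatures = 30, useCache = TRUE)
  b <- runIBCGA(config = cfg, fitnessFn = toyFitness(w, 0.2),
                nFeatures = 30, useCache = FALSE)
  expect_identical(a$trajectory$bestFitness, b$trajectory$bestFitness)
  expect_identical(a$best$featureIdx, b$best$featureIdx)
  expect_identical(a$best$C, b$best$C)
  # the cache saves work
  expect_lt(a$evaluations, b$evaluations)
})

test_that("repeated runs summarize fitness across independent seeds", {
  w <- runif(25)
  cfg <- ibcgaConfig(rStart = 3, rEnd = 5, nPop = 10, gMax = 6, seed = 30,
                     runs = 3)
  rr <- repeatedRuns(se = NULL, cfg, fitnessFn = toyFitness(w, 0.3),
                     nFeatures = 25)
  expect_length(rr$fitnesses, 3L)
  expect_identical(rr$meanFitness, mean(rr$fitnesses))
  expect_gte(max(rr$fitnesses), rr$meanFitness)
  expect_identical(rr$best$fitness, rr$runs[[rr$bestRun]]$best$fitness)
  one <- repeatedRuns(se = NULL, ibcgaConfig(rStart = 3, rEnd = 5,
                                             nPop = 10, gMax = 6,
                                             seed = 31, runs = 1),
                      fitnessFn = toyFitness(w, 0.3), nFeatures = 25)
  expect_identical(one$sdFitness, 0)
  expect_identical(one$meanFitness, one$best$fitness)
})
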