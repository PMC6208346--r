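---
title: "Selecting stage-discriminating miRNA signatures with stageSig"
author: "stageSig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stage-discriminating miRNA signatures with stageSig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageSig)
```

## The problem

Bulk miRNA expression cohorts of solid tumours typically carry a few
hundred features (mature miRNAs) over a few hundred patients, and a binary
clinical contrast of interest — here the pathological stage group, *early*
(stages I–II) versus *advanced* (III–IV). Individual miRNAs shift only
subtly between the groups: differences of 0.1–0.4 units on a log2-like
scale against within-group SDs of 0.4–1.4, i.e. standardized effect sizes
well below one half. No single feature classifies patients usefully; a
small multivariate *signature* can. stageSig implements a wrapper
feature-selection approach for this setting: a soft-margin RBF support
vector machine (SVM) evaluated by stratified cross-validation serves as the
fitness function of an inheritable bi-objective combinatorial genetic
algorithm (IBCGA) that searches the space of fixed-size feature subsets
jointly with the SVM hyper-parameters.

## The model and the search

The classifier is the standard soft-margin SVM,
$\min_{w,b,\xi} \tfrac12\lVert w\rVert^2 + C\sum_i \xi_i$, with a Gaussian
kernel $K(x,z)=\exp(-\gamma\lVert x-z\rVert^2)$. The kernel choice is an
inference: the method evolves both $C$ and $\gamma$, which only makes sense
for an RBF-type kernel. Each GA chromosome carries $n$ binary feature
genes plus two 4-bit genes placing the hyper-parameters on the standard
libsvm grids $C = 2^{c-5} \in \{2^{-5},\dots,2^{10}\}$ and
$\gamma = 2^{g-15} \in \{2^{-15},\dots,2^{0}\}$.

A chromosome's fitness is its pooled k-fold cross-validation accuracy (in
percent): per fold the SVM is trained on the remaining folds and predicts
the held-out fold; the pooled confusion table over all folds gives the
accuracy. Pooling (rather than averaging per-fold accuracies) is exactly
equivalent for equal fold sizes and better behaved for unequal ones; the
per-fold values are reported alongside. One fold assignment, fixed at the
start of a run, is shared by every fitness evaluation so that chromosomes
are compared on identical partitions and fold noise cannot masquerade as
fitness differences.

The IBCGA evolves subsets of *fixed* cardinality $r$ and sweeps
$r = r_\mathrm{start} \dots r_\mathrm{end}$ (defaults 10–50):

1. **Initialization** — `nPop` chromosomes with exactly $r_\mathrm{start}$
   random active genes and uniform parameter genes.
2. **Selection** — binary tournaments build a mating pool.
3. **Orthogonal-array crossover** — both parents are cut into
   `gammaSegments` (default 7) contiguous segments spanning feature and
   parameter genes. The rows of the 2-level orthogonal array
   $L_8(2^7)$ assemble 8 candidates mixing parental segments; each is
   repaired to cardinality $r$ and evaluated. Factor main effects (mean
   candidate fitness per segment level) predict one further candidate
   assembled from each segment's better level. The two fittest distinct
   chromosomes among candidates, prediction and parents become the
   offspring, so crossover never loses the better parent.
4. **Mutation** — a swap of one active and one inactive gene (preserving
   $r$) applied to a fraction (default 20%) of individuals, never to the
   current best; each 4-bit gene is re-randomized uniformly with
   probability 0.1 or takes a ±1 creep step with probability 0.3. The
   creep component is what lets elitist selection hill-climb the parameter
   grids, where neighbouring $C$ or $\gamma$ values have strongly
   correlated fitness; uniform re-draws alone explore the 16-point grids
   far too slowly for exact convergence.
5. **Replacement** — generational, with the elite re-inserted if the new
   population would otherwise regress.
6. **Inheritance** — at the end of a phase, every individual gains one
   random inactive feature and the population enters phase $r+1$.

The final solution is the per-phase best with maximal fitness, ties broken
toward smaller $r$ — the bi-objective preference for compact signatures.
Fitness values are memoized by (subset, $C$, $\gamma$); memoization is
purely an optimization and cannot change trajectories because the fitness
is deterministic given the folds.

### The generation budget

The reference parameterization gives a generation cap $G_{\max} = 60$
without stating whether it bounds each cardinality phase or the whole
sweep. `ibcgaConfig(gMaxMode=)` implements both readings. `"total"`
(default) splits $G_{\max}$ as evenly as possible across the
$r_\mathrm{end}-r_\mathrm{start}+1$ phases and is the cheap, predictable
option. `"per-phase"` runs up to $G_{\max}$ generations in every phase and
pairs naturally with `patience`, which ends a phase after a fixed number of
generations without elite improvement. For *search-quality* experiments
(e.g. planted-feature recovery below) we use `"per-phase"` with a small
patience: with the total-budget reading a reduced configuration such as
$G_{\max}=15$ over 11 phases leaves roughly one generation per
cardinality, which is not a meaningful evolutionary search, and the
patience rule concentrates effort where fitness is still improving. The
swap-mutation count and the 20% mutation fraction, the 0.8 crossover rate,
the tournament size 2 and the segment count 7 are otherwise-unstated
details fixed here as package defaults.

## Ranking and ablation of a selected signature

**MED ranking.** Main-effect-difference analysis scores each signature
member by an orthogonal experimental design over *include/exclude* levels:
with $m$ features, the $2^{\lceil\log_2(m+1)\rceil}$-run 2-level array
defines a batch of subsets; each row's included subset is evaluated by the
same cross-validated SVM (empty rows score 0), and
$\mathrm{MED}(j) = \bar F(j{=}1) - \bar F(j{=}0)$, the difference in mean
row fitness with feature $j$ in versus out. Features are ranked by
descending MED, ties broken lexicographically. The OED-style main-effect
definition is a reconstruction — the absolute scale of MED scores is tied
to the design and cohort, so only the *ranks* should be compared across
analyses. A 34-feature signature needs a 64-run array; the construction
(Sylvester-Hadamard) supports any factor count.

**Knockout.** Complementarily, `knockoutAnalysis()` removes one feature at
a time and reports the drop in pooled CV accuracy in percentage points,
with $(C,\gamma)$ and folds held fixed so the difference isolates the
feature's contribution rather than re-optimization effects. MED measures a
feature's average marginal effect over many subset contexts; knockout
measures its effect in the full-signature context only. On redundant
features the two can disagree legitimately — a duplicated informative
feature has attenuated MED (its copy covers for it in half the
experiments) and near-zero knockout.

**Group statistics.** `groupStats()` reports per-class means and SDs
(denominator $n-1$) on the pre-normalization scale whenever
`normalizeExpression()` kept it, because group summaries on z-scored
values are not interpretable in expression units.

## Baselines

`infoGainRank()` implements the classical attribute ranking:
information gain $H(\text{labels}) - H(\text{labels}\mid\text{feature})$
after Fayyad–Irani MDL discretization (recursive entropy-minimizing binary
splits accepted by the MDL criterion), falling back to 10 equal-frequency
bins for features where MDL accepts no split. `runBaselines()` evaluates
random forest, a single-hidden-layer perceptron, a linear-kernel SVM,
naive Bayes and a CART tree — delegated to their standard R
implementations at (near-)default settings — on the information-gain
selection under the *same* stratified folds, giving the conventional
comparison table.

## The synthetic cohort generator

`simulateCohort()` emulates the structure of the motivating cohort type: a
balanced two-class cohort (defaults 193 + 193 samples, 503 features) on a
log2-like scale. *Planted* features are Gaussian with class-specific
(mean, SD) taken by default from `plantedTemplate()` — ten realistic
(mean ± SD) pairs per class with shifts of 0–0.4 units, i.e. standardized
effects of 0–0.3. *Background* features draw a single class-independent
mean from $U(0, 14)$ and SD from $U(0.4, 1.4)$ per feature — the span of
the template values — and thus carry no class signal. Values may dip
slightly below zero on this scale; they are deliberately not clipped since
per-feature normalization makes the offset irrelevant. Gaussianity is the
weakest assumption compatible with mean ± SD summaries; the generator does
not model miRNA–miRNA correlation, count-level sequencing noise, or batch
structure, so passing recovery tests here demonstrates correctness of the
search machinery, not performance on real sequencing data. Because the
template's own effect sizes are very small, `effectMultiplier` scales the
planted shifts for calibration experiments; recovery tests use a
standardized shift of 1.0, which is large for a single miRNA but produces
cohorts where subset search is genuinely non-trivial (see below).

`permuteLabels()` yields the matched null cohort (labels permuted, matrix
untouched) used for calibration: selection on a permuted cohort must not
beat chance on truly held-out data.

## Numerical and degenerate-input choices

* Normalization standardizes with the population SD (denominator $n$),
  the standard-scaler convention; constant features map to all-zero rather
  than dividing by zero. `log2p1_zscore` refuses negative input (it is
  meant for counts-like scales); use `zscore` for data already on a
  log-like scale, including simulated cohorts.
* Zero-denominator MCC is defined as 0; zero-denominator sensitivity or
  specificity is reported as `NA` (undefined) rather than silently 0.
* AUC integrates the empirical ROC by trapezoids with tied scores grouped,
  which makes it exactly the normalized Mann–Whitney $U$ (ties counted
  half).
* Stratified folds spread per-class remainders greedily over the smallest
  folds, so both the class split per fold and the overall fold sizes stay
  within one sample of balance.
* Chromosomes with an empty feature subset get fitness 0, creating repair
  pressure instead of an error deep in the GA loop.
* SVM decision scores are signed distances to the hyperplane oriented so
  that larger means more advanced-like; no probability calibration is
  applied anywhere.
* All randomness flows from explicit seeds through local RNG scopes that
  restore the caller's `.Random.seed`; a pipeline's global seed fans out
  to per-stage seeds by fixed offsets recorded in the run manifest.

## Problem sizes used in the test-suite experiments

The packaged experiments run at desk scale, chosen to exercise every code
path while keeping the suite quick: recovery experiments use 200 features
(10 planted at standardized shift 1.0) with 100 samples per class under a
reduced GA configuration (`nPop = 20`, `gMax = 15` per phase with
patience 3, `r = 5..15`); null-calibration cohorts use 100 features with
60 samples per class; MED/knockout coherence uses 8-feature signatures
with one feature planted at standardized shift 1.5. With ten planted features at shift 1.0 the Bayes
error of the full planted set is about 1%, so held-out accuracies well
above 0.75 are attainable whenever the search recovers most of the planted
set.

A caveat worth stating plainly: with a couple of hundred candidate
features and 200 samples, maximizing cross-validated accuracy over subsets
*overfits the folds* — some noise features correlate with the labels by
chance and genuinely raise in-sample CV fitness. The selected signature
therefore typically mixes most of the planted features with a few such
lucky passengers, its CV fitness overstates generalization, and held-out
evaluation on an independently simulated cohort is the honest metric. This
is a property of wrapper selection itself, not of this implementation, and
it is why the package always separates fitness (internal CV) from held-out
assessment in its own experiments.

## Known limitations

* Binary classification only; no multi-class chromosomes.
* The GA is single-population and single-threaded; no island models.
* MED scores are design-relative; compare ranks, not magnitudes.
* The baselines are convenience delegates at library defaults, not tuned
  competitors.
* The generator's independence assumption makes planted-recovery tests
  easier than real cohorts where informative features correlate.
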