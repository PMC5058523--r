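---
title: "Modeling invasion risk with presence-background suitability and dispersal-constrained projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling invasion risk with presence-background suitability and dispersal-constrained projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A species endemic to a biodiversity hotspot that begins expanding into an
agricultural crop's cultivation areas poses a double-edged management
problem: eradication threatens an endemic, inaction threatens livelihoods.
`invasim` implements the quantitative chain that supports early management
decisions for such a system — for instance a forest snail spreading into
cardamom plantations: where is habitat suitable for the invader and for the
crop, how much do those areas overlap, which cultivated cells face the
highest invasion pressure, and how far can a poor disperser actually get as
the environment shifts?

The package is organized as a pipeline over plain-text rasters and point
tables:

1. **Collinearity screening** of environmental predictor layers.
2. A **presence-background maximum-entropy suitability model** with
   replicate evaluation (AUC, TSS) and MTSS thresholding.
3. **Overlap statistics** between the two species' suitable areas.
4. A **three-component invasion-risk score** on crop-suitable cells.
5. A **cellular-automaton dispersal projection** through a future
   environmental series.
6. A **demographic cross-check** of predicted suitability classes.

Because real occurrence records and global raster products are external,
every stage is exercised against a **synthetic landscape generator** with
known ground truth; the package's tests are parameter-recovery and
invariant checks on those landscapes.

# The suitability model

With presence-only data, the model contrasts cells where the species was
recorded against a background sample of the landscape. Over the background
cells $x$ the model is the Gibbs distribution

$$ q_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z(\lambda)}, \qquad
   Z(\lambda) = \sum_{x \in \text{bg}} e^{\lambda \cdot f(x)}, $$

with features $f$ built from the predictors (linear, quadratic, and
pairwise-product terms by default; no hinge or threshold features).
Features are standardized to mean 0, SD 1 over the background, so the
per-feature penalty scale is the background SD of the raw feature. The
weights minimize the convex penalized log-loss

$$ J(\lambda) = -\overline{\lambda \cdot f}_{\text{presence}}
   + \log Z(\lambda) + \frac{\beta}{\sqrt{m}} \sum_j |\lambda_j|, $$

where $m$ is the number of presence cells after thinning to one per cell.
The $1/\sqrt{m}$ factor is the usual lasso-style calibration: without it, a
unit multiplier would zero out every coefficient regardless of signal,
because the gradient at $\lambda = 0$ is a standardized presence mean and
rarely exceeds 1. With it, the default `reg_beta = 1` gives a usable model
at typical sample sizes while still pruning uninformative features.

Optimization is cyclic prox-Newton coordinate descent with a backtracking
safeguard, iteration cap $10^4$ cycles, and relative objective tolerance
$10^{-8}$. The objective is convex, so runs from different starting points
agree; the test suite asserts agreement to $10^{-6}$ relative. Randomness
enters only through sampling (occurrences, splits, background), never
through the optimizer.

Two output scales are provided. The **raw** output is $q_\lambda$
normalized to sum to 1 over the background sample. The **logistic** output
is $q e^{H} / (1 + q e^{H})$, with $H$ the entropy of the fitted background
distribution — the conventional transform to a bounded habitat-suitability
index in $[0, 1]$, which all later thresholding assumes.

## Evaluation and thresholding

Replicate evaluation repeats: a random presence split (default 70/30
train/test), a fresh background sample, a fit on the training presences,
then

* **AUC** — rank-based (Mann–Whitney) with ties counted one half,
  background cells serving as the negative class;
* **MTSS** — the threshold maximizing sensitivity + specificity over the
  training scores, evaluating every unique score as a `>=` cut, ties
  resolved toward the smallest threshold (the more inclusive suitable
  area — conservative for risk screening);
* **TSS** — sensitivity + specificity − 1 of the held-out presences at the
  replicate's MTSS threshold.

Summaries are means and standard deviations across replicates. Suitability
maps are binarized at MTSS; the conventional four map classes are class 0
below MTSS and equal-width tertiles of $[\text{MTSS}, 1]$ for
poor/medium/high — an explicit, monotone convention standing in for the
unstated manual breaks common in GIS workflows (configurable).

## Variable diagnostics

* **Percent contribution** sums the objective gains of the coordinate
  updates per predictor; a product feature's gain is split equally between
  its two parents (attribution for interaction terms is a convention, not
  an estimate).
* **Permutation importance** permutes one predictor's raw values across the
  evaluation cells (training presences plus background) and measures the
  drop in training AUC, normalized to 100.
* **Jackknife gains** refit with each predictor alone and each excluded.

# Collinearity screening

Pairwise Pearson correlations are computed over one common random sample of
non-nodata cells (default $10^4$). Pairs with $|r|$ strictly greater than
the threshold (default 0.7) are broken greedily, worst pair first, dropping
the lower-priority member; the priority ordering is the user's statement of
biological relevance (e.g. keeping soil pH over total exchangeable bases
because pH mechanistically affects shell formation in mollusks). Greedy
removal is deterministic and auditable; on clique-structured correlation
(blocks of mutually redundant layers, the situation the screen exists for)
it attains the maximum possible retained set, which the tests verify
against exhaustive subset enumeration. On adversarial correlation graphs a
greedy pass can retain fewer variables than the optimum; it never retains
an over-correlated pair.

# The invasion-risk score

Risk is defined on crop-suitable cells (the crop's binary map at its MTSS)
as the rescaled unweighted sum of three bounded components:

1. **Suitability** — the invader's categorical map (0–3) on those cells,
   rescaled to $[0, 1]$;
2. **Land cover** — 1 for natural forest classes (the invader's habitat),
   0 for transformed or degraded classes;
3. **Proximity** — planar Euclidean distance from each cell center to the
   nearest invader occurrence, rescaled so the closest cell scores 1 and
   the furthest 0.

The sum is rescaled to $[0, 1]$ (0 low risk, 1 high risk). Components are
individually bounded before summing so no single term dominates by scale;
the final rescale makes the map comparable across landscapes. Distances
are planar in map units — inputs are assumed co-registered and the package
deliberately treats map units as opaque (no reprojection, no great-circle
option). A constant input to any rescale maps to all zeros with a warning
rather than an error, keeping batch runs alive on degenerate layers.
High/low band counts per degree of latitude use a configurable cut
(default 0.5; any probability-scale split is defensible and none is
canonical).

# The dispersal automaton

Future occupancy is projected with a MIGCLIM-style cellular automaton on
suitability scaled to the integer 0–1000 range (`round(1000 * logistic)`).
Per dispersal step:

(a) occupied cells whose suitability fell below `rcThreshold` are
decolonized (they may be recolonized later — no permanent-extinction flag,
the simplest consistent rule);
(b) every unoccupied, non-barrier cell at or above the threshold is
colonized with probability
$1 - \prod_{\text{mature sources}} (1 - p \cdot k(d))$, with $p$ the
propagule-production probability and $k$ a kernel indexed by the rounded
center-to-center distance in cells;
(c) each mature cell attempts long-distance dispersal with probability
`lddFreq`, colonizing one uniformly chosen eligible cell at rounded
distance in `[lddMinDist, lddMaxDist]`;
(d) ages increment; colonists start at age 1 and mature at `iniMatAge`.

Defaults follow a poor-disperser parameterization: `rcThreshold = 600`,
4 environmental-change periods of 20 steps, maturity after 1 step, certain
propagule production, `lddFreq = 0.05`, `lddMinDist = 2`, `lddMaxDist = 0`,
5 replicates. Two defaults deserve comment:

* `lddMaxDist = 0` with `lddMinDist = 2` is contradictory (max below min);
  the package treats it as **LDD disabled**, warns, and leaves the
  override to configuration — failing soft on a published but inconsistent
  setting rather than guessing an intent.
* The kernel default is probability 1 at rounded distance 1 (which
  includes diagonals) and 0 beyond: one cell per step, the minimal
  faithful choice for a poor disperser. It is a plain numeric vector in
  the configuration.

Three scenarios bracket reality: **unlimited** (every suitable cell
occupied each period, barriers ignored), **none** (no dispersal), and
**constrained** (the automaton with barriers, replicates averaged into a
consensus frequency map). For the no-dispersal scenario the package uses
cumulative persistence — an initial cell is occupied at period $k$ only if
it stayed suitable through periods $1..k$ and was not on a barrier — rather
than re-testing the initial set against each period independently. The
cumulative rule is what a no-dispersal population can actually do (a cell
lost to unsuitability cannot be recolonized without dispersal) and it
guarantees the scenario nesting *none ⊆ constrained ⊆ unlimited* at every
period, which the tests check on randomized landscapes. Barrier cells are
uninhabitable in all scenarios except the explicitly counterfactual
unlimited one.

# The synthetic landscape generator

The generator is first-class, tested code: every pipeline input can be
materialized with known ground truth.

* **Predictor stacks** — white Gaussian noise convolved with a uniform
  kernel (default radius 3 cells) for spatial autocorrelation, linearly
  mixed across layers to plant cross-correlations, then standardized.
  Kernel smoothing was chosen over variogram simulation: it is
  dependency-light and sufficient for recovery tests.
* **Truth surfaces** — logistic in linear and quadratic terms of chosen
  layers. The strong-signal condition used in recovery tests is
  `4*env1 - 3*env2 - 7`: a sharply delimited niche occupying roughly 8% of
  the landscape, the regime where presence-background discrimination is
  actually testable (a species suitable over a third of the map caps the
  achievable AUC near 0.83 regardless of fit quality, because a random
  presence and a random background cell then frequently tie).
* **Occurrences** — cells drawn without replacement with probability
  proportional to suitability × an optional effort-bias grid, one point
  per cell at the cell center.
* **Land cover** — smoothed noise thresholded at the quantile matching a
  target forest fraction, giving spatially clumped patches.
* **Future series** — additive per-period drift on chosen layers. No
  attempt is made to emulate circulation-model structure; the projection
  machinery consumes any co-registered raster series.
* **Demography** — site-level adult and juvenile densities increasing
  linearly in suitability with configurable slope and Gaussian noise,
  truncated at zero.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: observer-driven spatial sampling bias
beyond an explicit bias grid, non-stationary autocorrelation, interactions
among more than two predictors, measurement error in the predictor layers
themselves, and biotic interactions. Recovery results on these landscapes
demonstrate correctness of the machinery, not field-level predictive skill.

# Problem sizes and defaults

The default pipeline configuration runs a 60×60 landscape with 6
predictors (two driving the invader, one additional for the crop, and one
planted near-duplicate pair exercising the screen), 150 invader and 200
crop occurrences, a 2,000-cell background, 5 evaluation replicates, a
4-period future series, and 16 value-stratified demography sites — sizes
chosen so a full run completes in seconds while every stage operates above
its small-sample floors. Recovery and calibration checks use 100×100
landscapes with 500 presences and 5,000 background cells, 10 replicates or
seeds per property. Sub-seeds per stage are derived by stable hashing of
stage names, so adding or removing a stage does not shift another stage's
randomness, and two runs with the same configuration and seed are
bit-identical down to artifact hashes.

# Numerical conventions

* Cell centers at `(xmin + (col - 0.5) * cell, ymax - (row - 0.5) * cell)`;
  point-in-cell tests use half-open intervals so boundary points belong to
  exactly one cell.
* Nodata is `NA` internally and a sentinel (default −9999) only in files;
  operations that mix grids intersect nodata masks.
* ASCII-grid round trips are byte-exact under the writer's 15-significant-
  digit format.
* MTSS ties go to the smallest threshold; the `>=` decision rule is fixed
  package-wide.
* Welch's unequal-variance t-test for demography contrasts (robust to the
  unequal group sizes a category design produces); ratio parameters are
  undefined at zero denominators and excluded with a reported count.

# Known limitations

* No reprojection or resampling: all inputs must share one grid.
* No hinge/threshold/categorical features in the suitability model; sharp
  truth responses are approximated by quadratic/product terms.
* Greedy screening is order-optimal only on block-structured correlation.
* The automaton does not implement age-dependent propagule production
  curves, seed banks, or suitability-scaled colonization probability;
  eligibility above `rcThreshold` is binary.
* Distances are planar in map units; on geographic grids spanning many
  degrees of latitude this distorts east–west distances.
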