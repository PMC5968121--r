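---
title: "Methods: presence-only niche modelling and land-cover scenario forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only niche modelling and land-cover scenario forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

## The problem

Invasion managers need maps of where an established invasive plant can
live now and where it will be able to live under future climate and
land-cover conditions. The data available are almost always
*presence-only* occurrence records — places where the species was seen,
with no confirmed absences — together with gridded environmental
predictors (climate, topography, land cover). `nichecast` implements the
full analysis chain for this setting: a maximum-entropy habitat model
with complexity tuning, multi-metric evaluation, a Markov-chain /
multi-layer-perceptron land-cover simulation, and scenario-wise
range-change accounting, plus a synthetic-landscape generator with known
truth so that every stage can be validated end to end without any
external download.

## The maximum-entropy model

Let $f(x) \in [0,1]^J$ be a vector of *features* — transformations of the
raw predictor values at cell $x$ — and let the background $B$ be a random
sample of landscape cells characterising what environments are
available. The model is the Gibbs distribution over the background

$$q_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z_\lambda},
  \qquad Z_\lambda = \sum_{x \in B} e^{\lambda \cdot f(x)},$$

and the weights maximise the L1-penalised log-likelihood of the
presences $P$:

$$\ell(\lambda) = \frac{1}{|P|}\sum_{x \in P} \lambda \cdot f(x)
  - \log Z_\lambda - \sum_j \beta_j |\lambda_j|.$$

This is the maximum-entropy estimate: among all distributions whose
feature expectations match the presence sample means (up to the
$\beta_j$ slack), it is the one closest to uniform. The per-feature
penalties are $\beta_j = \beta \cdot c_{k(j)}(n) \cdot s_j/\sqrt{n}$,
where $\beta$ is the user's regularisation multiplier, $c_k(n)$ a
per-feature-class base penalty interpolated by presence sample size
(`regularizationDefaults()`, an editable table), $s_j$ the presence-sample
standard deviation of the feature, and $n$ the presence count.

### Feature classes

With scaled value $s = (v - lo)/(hi - lo)$ (bounds frozen from the
training support):

| class | definition | role |
|---|---|---|
| L | $s$ | mean constraint |
| Q | $s^2$ | variance constraint |
| P | $s_a s_b$ | pairwise interaction |
| T | $\mathbb{1}(v > t)$ | step response |
| H | $\max(0, v-t)/(hi-t)$ | piecewise-linear response |
| C | $\mathbb{1}(v = c)$ | categorical level indicator |

T/H knots sit at 10 equally spaced interior quantiles of the training
values per variable (the `knots` argument); categorical variables always
expand to a complete set of level indicators. In projection, raw values
outside the frozen bounds are clamped into them — the extrapolation rule
used when the model meets novel scenario climates.

### Fitting

`fitMaxent()` uses greedy coordinate-wise ascent: each update picks the
feature with the largest penalised directional gradient (ties broken by
the lowest feature index), takes a soft-thresholded Newton step, and
halves the step until the objective does not decrease. All normaliser
arithmetic runs through log-sum-exp, so large weights cannot overflow.
Iteration stops when the improvement per update falls below the
convergence tolerance (default $10^{-6}$) or after `maxIter` updates
(default 5,000; the model is then flagged unconverged). The recorded
"gain" is the regularised training gain — mean presence log-probability
above the log-uniform baseline, minus the penalty — which is
non-decreasing by construction; the unpenalised gain is reported
separately (`trainingGain()`). Per-update gain changes are credited to
the updated feature and drive `percentContribution()` (product-feature
credits split evenly between their two parents; negative variable totals
are clamped at zero before normalising to 100).

The suite verifies the optimiser against an independent L-BFGS-B
maximiser of the identical objective (split positive/negative
parameterisation) on randomly generated instances of up to 5 features
and 50 cells, with objective agreement to $10^{-6}$, and verifies
parameter recovery against landscapes generated from a known log-linear
truth. One caveat worth knowing: the linear and quadratic features of
the same variable are strongly collinear ($r \approx 0.97$ on a scaled
uniform spread), so with a few thousand sampled presences the individual
weights wander along that ridge even though the fitted *distribution* is
essentially exact; the recovery test therefore measures the relative L2
distance of the weight vector averaged over repeated presence draws.

### Outputs

`predictRaw()` returns $q_\lambda$ relative to the training normaliser
(summing to 1 over the training background). `predictLogistic()` maps it
to $(0,1)$ via $c\,q/(1 + c\,q)$ with $c = e^{H}$, $H$ the entropy of
the fitted raw distribution: a cell whose raw probability equals the
"typical site" value $e^{-H}$ scores exactly 0.5. `responseCurve()`
sweeps one variable across its training range with the others held at
their background means (modal class for categorical variables).

## Model selection by AICc

`tuneMaxent()` enumerates every non-empty subset of the feature classes
against a grid of regularisation multipliers (defaults: subsets of
{L, Q, H, P, T} × {0.1, 1, 2, …, 10} = 341 candidates), fits each on the
full occurrence set, and scores

$$\mathrm{AICc} = -2\ln L + 2k + \frac{2k(k+1)}{n-k-1},$$

with $\ln L$ the summed log of raw scores standardised to sum to 1 over
*all landscape cells* (the ENMeval/Warren–Seifert convention; the
likelihood support is a modelling choice the criterion's name alone does
not fix), and $k$ the count of features with nonzero weight after L1
fitting. Candidates with $n \le k+1$ are invalid. Ties break to smaller
$k$, then smaller multiplier, then the lexicographically smaller feature
set — so a candidate whose extra feature class was entirely zeroed out
(an exact objective tie) always loses to the smaller specification.

A known property of this criterion, visible in the test suite: at
moderate sample sizes (hundreds of presences) spurious threshold or
hinge features can capture sampling noise worth roughly 1–2 log-likelihood
units per active feature, close to the 2-per-parameter AICc price, so
selection among near-equivalent candidate shapes is itself noisy even
when the generating truth is in the candidate set. The selected models
are functionally close; the selected *labels* fluctuate.

## Evaluation

* **Rank AUC** (`rankAUC()`): the Mann–Whitney probability that a random
  presence outranks a random background point, ties counting ½. Bands
  (`aucBand()`): 0.5–0.6 Failed, 0.6–0.7 Poor, 0.7–0.8 Fair, 0.8–0.9
  Good, 0.9–1 Excellent, with boundary values assigned to the upper band
  (a deterministic resolution of ranges that are ambiguous at their
  boundaries); below 0.5 is "worse than random".
* **Continuous Boyce Index** (`boyceIndex()`): 101 overlapping windows of
  width 10% of the landscape suitability range (the continuous
  formulation needs a window scheme; both numbers are configurable);
  windows with zero expected fraction are dropped, at least 3 must
  remain; CBI is the Spearman correlation of predicted-to-expected
  ratios against window midpoints, hence bounded in $[-1, 1]$ and
  invariant under monotone rescaling of the scores.
* **Jackknife gains** (`jackknifeGains()`): refits with each variable
  omitted and alone, reusing the selected classes and multiplier,
  reporting unpenalised training gains.
* **Percent contribution** (`percentContribution()`): accumulated gain
  credits per source variable, normalised to 100.

## Replicates, thresholding and scenarios

`runReplicates()` runs 20 replicates by default, each a seeded random
75/25 train/validation partition. The split is *without* replacement
(every record on exactly one side) — resampling percentages and
bootstrap-with-replacement are mutually contradictory demands, so the
percentage semantics win and `method = "bootstrap"` is available as an
option. The working suitability surface is the cell-wise mean of the
replicate maps.

The binarisation threshold $\tau_{10}$ (`tenPercentileThreshold()`) is
the ascending order statistic at rank $\lceil 0.10\,n \rceil$ of the
training-presence suitabilities — no interpolation, so with 100 distinct
values exactly 9 fall strictly below it. It is computed once from the
current-data mean map and reused for every scenario
(`projectScenario()`): range change must be measured against a fixed
decision rule, though re-thresholding per scenario is a one-line option.
Percent range change is $100(\mathrm{suitable}_{future} -
\mathrm{suitable}_{current})/\mathrm{suitable}_{current}$, computed from
mean maps (not replicate-wise and averaged — the other defensible
choice). Scenario stacks swap climate layers and the land-cover layer
for the simulated future map, keeping topography fixed.

## Land-cover simulation

`crosstabTransition()` estimates the class transition matrix from two
dated maps; classes absent at the first date persist by assumption
(identity rows). `scaleTransition()` raises the matrix to the real power
`targetYears / intervalYears` by eigendecomposition — the stationarity
assumption that per-interval transition behaviour is constant. A
ten-year matrix projected 35 years is the power 3.5; tiny negative
entries from the decomposition (magnitude below $10^{-8}$) are clipped
and rows renormalised, and a numerically non-diagonalisable matrix falls
back to repeated multiplication with linear interpolation of the
fractional step (flagged in the result's `method` attribute).

`trainTransitionMLP()` fits one feed-forward network per source class
(single hidden layer of 10 logistic units by default, softmax outputs,
trained via `nnet`, which optimises by BFGS rather than stochastic
gradient descent) on a balanced, seeded sample of transitioned and
persistent cells, yielding one potential surface per observed
transition. Transitions never observed between the two dates are not
modelled — zero-probability pairs stay zero.

`transitionDemand()` integerises expected per-class conversions by the
largest-remainder rule (totals conserve exactly);
`allocateChange()` converts, per transition in descending demand order,
the demanded number of highest-potential source cells (seeded random
tie-breaks), each cell at most once. Cross-tabulating input against
output reproduces the demand exactly, and total cell count is conserved
by construction.

## The synthetic generator

`simulatePredictors()` builds spatially autocorrelated continuous
predictors as Gaussian-smoothed white noise (kernel standard deviation
`smoothing` cells, default 5), empirically whitened and mixed through
the symmetric square root of the target correlation matrix so the
sample correlations hit their targets essentially exactly (positive
semi-definite targets only; perfectly correlated layers are allowed and
come out identical up to affine transform). The categorical land-cover
layer cuts an independent smooth field into quantile-balanced patchy
classes with IDs 1..k. `truthSuitability()` evaluates a known log-linear
truth and normalises it to sum to 1; `samplePresences()` draws cell
centres with replacement proportionally to it; cell centres (no
within-cell jitter) make rarefaction behaviour exactly predictable.
`simulateLandcoverPair()` draws the first map i.i.d. from a class prior
(uniform by default, configurable) and applies the transition matrix
cell-wise, optionally re-weighted by per-transition driver effects and
renormalised.

What this emulates: smooth climatic-style gradients with controllable
collinearity, habitat-driven presence sampling, and Markovian land-cover
change modulated by drivers. What it does not: sampling bias and
georeferencing error in occurrence records, non-stationary transition
behaviour, anisotropic or long-range spatial structure, and real
geography (no projections or geodesy — the grid is planar). Passing
tests demonstrate that the estimators recover known truth under the
sampling model they assume, not that any particular real landscape
satisfies those assumptions.

## Numerical and interface choices

* Coordinates: planar, north-up, row 1 at the top; origin at the
  lower-left corner; points bin into cells by half-open intervals
  `[edge, edge + cellSize)`. The first point (input order) survives
  rarefaction in each cell, making `cleanAndRarefy()` deterministic and
  idempotent.
* Occurrence counts in the bundled synthetic configurations are
  configurable rather than fixed: realistic survey datasets shrink
  substantially under cell-level rarefaction (a few hundred raw records
  to under a hundred cells is typical), so no single count is canonical.
* Collinearity filtering (`correlationFilter()`) implements only the
  statistical rule — greedy elimination above the |r| cutoff (default
  0.85), dropping the member with the higher mean absolute correlation —
  with a user-supplied priority list as the hook for expert preference,
  which is not otherwise implementable. Correlation is measured over the
  union of presence and background cells (the model-fitting support).
  Background points may share cells with presences by default
  (`exclude` turns that off).
* Rasters travel as ESRI ASCII Grid, a plain-text exchange format whose
  nodata semantics are honoured bit-exactly on round trip; occurrences
  as x,y CSV; models as a plain-text lambdas file; reports as CSV/JSON.
* All randomness flows through explicit integer seed arguments
  (`withr::with_seed`), so every generator, partition, network
  initialisation and tie-break is bit-reproducible; `runPipeline()`
  derives per-stage seeds deterministically from one master seed.
* The bundled reference table of Snowdonia land-cover class areas
  (`extdata/snowdonia_landcover_change.csv`) ships with its printed
  percent-change column, but `areaChange()` always recomputes change
  from the areas: one printed row (herbaceous cover, +28.7%) disagrees
  with the +31.7% its own areas imply, and the recomputation is treated
  as authoritative. Class labels in that table follow the tabulated
  IDs (8 = mosaic tree and shrub, 6 = needleleaved evergreen trees);
  prose accounts sometimes swap the two labels.
* Test and vignette problem sizes (20×20 to 80×80 landscapes, hundreds
  to a few thousand presences, 300×300 grids for transition round
  trips) were chosen as the smallest sizes at which the statistical
  checks have adequate power.

## Known limitations

* No cumulative maxent output, no sampling-bias ("bias file")
  weighting, no spatial block cross-validation, no TSS/kappa/partial
  AUC, no MESS extrapolation surfaces.
* The AICc likelihood uses the raw (not logistic) scores; comparing
  AICc values across different landscapes is meaningless.
* The MLP stage models each source class independently and does not
  impose spatial contiguity on allocated change (no cellular-automaton
  filter).
* GeoTIFF input is not parsed; convert to ASCII grid first.
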