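# nichecast

Presence-only niche modelling and land-cover scenario forecasting for
invasion ecology.

Managers of an established plant invasion need two maps: where the
species can live today, and where it will be able to live under future
climate and land cover. The data are presence-only occurrence records
and gridded environmental predictors. `nichecast` implements the whole
analysis chain for that setting, plus a synthetic-landscape generator
with known truth so every stage is testable end to end without any
external data:

* **Maximum-entropy habitat model.** The suitability of cell `x` is the
  Gibbs distribution `q(x) = exp(λ·f(x)) / Z` over a background sample,
  with features `f` built from linear (L), quadratic (Q), product (P),
  threshold (T) and hinge (H) transforms of the predictors plus
  categorical indicators. Weights maximise the L1-penalised
  log-likelihood `Σ_presence log q(x) − Σ_j β_j |λ_j|` by greedy
  coordinate-wise ascent; a logistic transform anchored at the typical
  site (`c·q/(1+c·q)`, `c = exp(H)`) gives suitability in (0, 1).
* **Complexity tuning.** All non-empty feature-class subsets ×
  regularisation multipliers (default 31 × 11 = 341 candidates) scored
  by small-sample-corrected AIC, `AICc = −2 lnL + 2k + 2k(k+1)/(n−k−1)`,
  with `k` the nonzero-weight count; lowest AICc wins.
* **Evaluation.** Rank AUC with the conventional qualitative bands, the
  Continuous Boyce Index (Spearman correlation of windowed
  predicted-to-expected ratios, in [−1, 1]), jackknife variable
  importance, percent contribution.
* **Replication and thresholding.** 20 seeded 75/25 train/validation
  replicates, cell-wise mean map, ten-percentile training presence
  threshold `τ₁₀` for binary suitable/unsuitable maps.
* **Land-cover simulation.** Cross-tabulated Markov transition matrix
  from two dated maps, real matrix powers for arbitrary horizons, MLP
  transition potentials on driver variables (via `nnet`), and exact
  integer change allocation.
* **Scenario accounting.** Replicate models projected onto scenario
  stacks (clamped to training bounds), binarised at the current-data
  `τ₁₀`, and percent range change `Δ = 100(future − current)/current`.

Rasters travel as plain-text ESRI ASCII Grid, occurrences as x,y CSV;
`runPipeline()` drives the whole chain from a YAML config with one
master seed.

## Worked example

Simulate a landscape whose true suitability is log-linear and known,
then run the full analysis against it:

```r
library(nichecast)

cfg   <- landscapeConfig(rows = 60, cols = 60, nContinuous = 3,
                         nLandcoverClasses = 4, seed = 1)
stack <- simulatePredictors(cfg)
truth <- syntheticTruth(kind = c("L", "Q", "L"),
                        var  = c("env1", "env1", "env2"),
                        weight = c(6, -4, 3))
suit  <- truthSuitability(stack, truth)
occ   <- cleanAndRarefy(samplePresences(suit, 450, seed = 2), stack)
occ
#> OccurrenceSet: 414 point(s)
#>   - 450 presences sampled from truth
#>   - cleaned 450 -> 414: 36 duplicates, 0 masked/off-grid, rarefied to one per cell
bg <- sampleBackground(stack, 2000, seed = 3)

tune <- tuneMaxent(extractValues(stack, occ), extractValues(stack, bg),
                   landscape = stack, featureClasses = c("L", "Q", "H"),
                   regGrid = c(0.1, 1, 2, 5), knots = 5)
tune$best
#>    features regMultiplier k       lnL     AICc valid
#> 14       LQ             1 7 -3330.024 6674.325  TRUE

reps <- runReplicates(occ, bg, stack,
                      classes = strsplit(tune$best$features, "")[[1]],
                      regMultiplier = tune$best$regMultiplier,
                      n = 20, seed = 4)
evaluateModel(reps, stack, occ, bg, knots = 5)
#> AUC train 0.646 / test 0.638 (Poor), CBI 0.984
#> Percent contribution:
#>      env2      env1 landcover      env3
#>      53.8      37.9       5.9       2.4

tau     <- tenPercentileThreshold(
  gridValues(reps@meanMap)[cellFromXY(reps@meanMap, coords(occ))])
current <- binarizeMap(reps@meanMap, tau)
current
#> ThresholdedMap: threshold 0.3649, 2716 suitable cell(s) (75.4%)

layers <- stack@layers
layers$env1@values <- layers$env1@values + 1   # a uniform warming shift
projectScenario(reps, rasterStack(layers), "warm", tau, current)
#> ScenarioResult 'warm': 3154 suitable cell(s), range change +16.13%
```

Reading the output: AICc correctly selects the generating `LQ` feature
shape; the modest AUC reflects that rarefied presences cover a large
share of this small landscape (AUC measures separation from background,
so overlap caps it), while the near-perfect Boyce index (0.984) shows
the predicted gradient ranks habitat essentially exactly; the truth's
positive `env1` linear term makes the warming scenario expand the
binary range by +16.13% at the fixed current-data threshold.

The methods vignette (`vignettes/nichecast-methods.Rmd`) documents the
model, every tunable default, the numerical choices, and what the
synthetic generator does and does not emulate.

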