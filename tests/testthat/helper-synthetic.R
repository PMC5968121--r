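# Shared fixture builders -- everything is generated in code.

# A small two-predictor landscape with a categorical cover layer.
makeStack <- function(rows = 20, cols = 20, seed = 42, r = 0,
                      smoothing = 3, nClasses = 3) {
  cfg <- landscapeConfig(rows, cols, nContinuous = 2,
                         targetCorrelations = matrix(c(1, r, r, 1), 2, 2),
                         nLandcoverClasses = nClasses,
                         smoothing = smoothing, seed = seed)
  simulatePredictors(cfg)
}

# Continuous-only view of the same landscape.
makeContStack <- function(...) {
  st <- makeStack(...)
  rasterStack(st@layers[c("env1", "env2")])
}

# The canonical L+Q truth used by recovery experiments.
makeTruth <- function(w = c(6, -4, 3)) {
  syntheticTruth(kind = c("L", "Q", "L"),
                 var = c("env1", "env1", "env2"), weight = w)
}

# Tiny hand-built grid, row 1 = north.
toyGrid <- function(vals, mask = NULL, cellSize = 1, categorical = FALSE) {
  rasterGrid(vals, mask = mask, cellSize = cellSize, categorical = categorical)
}

# A bare FeatureMatrix around an explicit design matrix (for fit oracles).
bareFeatures <- function(M, kinds = rep("L", ncol(M))) {
  nf <- ncol(M)
  defs <- data.frame(kind = kinds, var = paste0("v", seq_len(nf)), var2 = NA,
                     knot = NA, level = NA, name = paste0("f", seq_len(nf)),
                     stringsAsFactors = FALSE)
  vs <- data.frame(var = paste0("v", seq_len(nf)), categorical = FALSE,
                   lo = 0, hi = 1, meanValue = 0.5, modalLevel = NA)
  new("FeatureMatrix", M = M, defs = defs, varSummary = vs, classes = "L")
}

# Numerically safe log-sum-exp for test-side oracles.
lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# Presence/background feature matrices for a fitted landscape experiment.
fitInputs <- function(stack, suitability, nPres, presSeed,
                      classes = c("L", "Q"), knots = 10) {
  bg <- sampleBackground(stack, prod(dim(stack)), seed = 1)  # all cells
  occ <- samplePresences(suitability, nPres, seed = presSeed)
  bf <- expandFeatures(extractValues(stack, bg), classes = classes,
                       knots = knots)
  pf <- expandFeatures(extractValues(stack, occ), reference = bf)
  list(pres = pf, bg = bf, occ = occ, bgPts = bg)
}
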