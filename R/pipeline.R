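#' @include AllClasses.R
NULL

#' Read a pipeline configuration from YAML
#'
#' The configuration drives [runPipeline()]. Top-level keys:
#' \itemize{
#'   \item `seed`: integer master seed (required); per-stage seeds are
#'     derived from it deterministically.
#'   \item `synthetic`: synthetic-landscape spec — grid shape,
#'     predictors, truth weights, land-cover transition process,
#'     presence count — or, alternatively, `paths` pointing at ASCII
#'     grid rasters and an occurrence CSV.
#'   \item `preprocessing`: `cutoff` (correlation filter), `background`
#'     (point count).
#'   \item `tuning`: `featureClasses`, `regGrid`, `knots`.
#'   \item `replicates`: `n`, `trainFrac`.
#'   \item `landcover`: `horizonYears`, MLP settings.
#'   \item `scenarios`: optional list of scenario entries, each with a
#'     `label` and per-layer additive `shift`s applied to the current
#'     climate layers (the simulated future land cover replaces the
#'     land-cover layer automatically).
#' }
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .validatePipelineConfig(cfg)
  cfg
}

.validatePipelineConfig <- function(cfg) {
  if (is.null(cfg$seed)) stop("pipeline config must set a seed")
  if (is.null(cfg$synthetic) && is.null(cfg$paths))
    stop("pipeline config needs either a synthetic spec or input paths")
  if (!is.null(cfg$paths)) {
    files <- unlist(cfg$paths[c("predictors", "occurrences")], use.names = FALSE)
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop(sprintf("referenced input file(s) not found: %s",
                   paste(missing, collapse = ", ")))
  }
  invisible(cfg)
}

.stageSeed <- function(seed, stage) {
  offsets <- c(landscape = 11L, landcoverPair = 23L, presences = 37L,
               background = 43L, mlp = 59L, allocate = 67L,
               replicates = 79L)
  (as.integer(seed) * 113L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes the two-step design end to end: Step I simulates (or
#' ingests) the land-cover history, cross-tabulates its transition
#' matrix, scales it to the projection horizon, trains MLP transition
#' potentials and allocates the projected land-cover map; Step II
#' preprocesses occurrences (clean, rarefy, background sample,
#' correlation filter), tunes feature classes and regularisation by
#' AICc, runs replicated fits, evaluates them (AUC, CBI, jackknife,
#' contributions), thresholds the mean map, and projects every
#' configured scenario, accounting percent range change. All artifacts
#' are written under `outputDir` along with a JSON run manifest. Any
#' stage failure aborts with the stage name; artifacts written before
#' the failure are retained.
#'
#' @param config configuration list (see [readPipelineConfig()]).
#' @param outputDir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config, outputDir) {
  .validatePipelineConfig(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outputDir, name)
    writer(path)
    outputs <<- c(outputs, name)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  syn <- config$synthetic
  # --- inputs ---------------------------------------------------------
  world <- stage("inputs", {
    if (!is.null(syn)) .synthesizeInputs(syn, seed)
    else .loadInputs(config$paths)
  })
  stack <- world$stack

  # --- Step I: land-cover simulation ---------------------------------
  lcCfg <- config$landcover
  horizon <- if (!is.null(lcCfg$horizonYears)) lcCfg$horizonYears else 35
  lc <- stage("landcover", {
    tm <- crosstabTransition(world$landcoverT1, world$landcoverT2,
                             intervalYears = world$intervalYears)
    tmH <- scaleTransition(tm, horizon)
    drivers <- rasterStack(stack@layers[!vapply(stack@layers, isCategorical,
                                                logical(1))])
    pots <- trainTransitionMLP(world$landcoverT1, world$landcoverT2, drivers,
                               hiddenSize = lcCfg$hiddenSize %||% 10,
                               maxit = lcCfg$maxit %||% 200,
                               seed = .stageSeed(seed, "mlp"))
    demand <- transitionDemand(tmH, world$landcoverT2)
    future <- allocateChange(world$landcoverT2, demand, pots,
                             seed = .stageSeed(seed, "allocate"))
    list(matrix = tm, scaled = tmH, potentials = pots, future = future)
  })
  emit("transition_matrix.csv", function(p)
    utils::write.csv(as.data.frame(lc$matrix@P), p))
  emit("landcover_future.asc", function(p) writeAsciiGrid(lc$future, p))
  emit("landcover_change.csv", function(p)
    utils::write.csv(classAreaChange(world$landcoverT2, lc$future), p,
                     row.names = FALSE))

  # --- Step II: preprocessing ----------------------------------------
  pre <- config$preprocessing
  prep <- stage("preprocess", {
    occ <- cleanAndRarefy(world$occurrences, stack)
    bg <- sampleBackground(stack, n = pre$background %||% 10000,
                           seed = .stageSeed(seed, "background"))
    support <- rbind(extractValues(stack, occ), extractValues(stack, bg))
    filt <- correlationFilter(stack, cells = support,
                              cutoff = pre$cutoff %||% 0.85,
                              priority = pre$priority)
    fStack <- rasterStack(stack@layers[filt$retained])
    list(occ = occ, bg = bg, filter = filt, stack = fStack)
  })
  emit("occurrences_clean.csv", function(p) writeOccurrences(prep$occ, p))
  emit("filter_report.csv", function(p) writeFilterReport(prep$filter, p))

  # --- tuning ---------------------------------------------------------
  tun <- config$tuning
  tune <- stage("tune", {
    tuneMaxent(extractValues(prep$stack, prep$occ),
               extractValues(prep$stack, prep$bg),
               landscape = prep$stack,
               featureClasses = tun$featureClasses %||% c("L", "Q"),
               regGrid = tun$regGrid %||% c(0.1, 1:10),
               knots = tun$knots %||% 10)
  })
  emit("selection_table.csv", function(p)
    utils::write.csv(tune$table, p, row.names = FALSE))

  # --- replicates + evaluation ---------------------------------------
  repCfg <- config$replicates
  reps <- stage("replicates", {
    runReplicates(prep$occ, prep$bg, prep$stack,
                  classes = strsplit(tune$best$features, "")[[1]],
                  regMultiplier = tune$best$regMultiplier,
                  n = repCfg$n %||% 20,
                  trainFrac = repCfg$trainFrac %||% 0.75,
                  knots = tun$knots %||% 10,
                  seed = .stageSeed(seed, "replicates"))
  })
  emit("suitability_current.asc", function(p)
    writeAsciiGrid(reps@meanMap, p))
  evalRep <- stage("evaluate", {
    evaluateModel(reps, prep$stack, prep$occ, prep$bg,
                  knots = tun$knots %||% 10)
  })
  emit("evaluation", function(p) writeEvaluationReport(evalRep, p))
  outputs <- c(setdiff(outputs, "evaluation"),
               "evaluation.json", "evaluation_jackknife.csv",
               "evaluation_contributions.csv")

  # --- threshold + scenarios -----------------------------------------
  tau <- stage("threshold", {
    presSuit <- reps@meanMap@values[cellFromXY(reps@meanMap, coords(prep$occ))]
    tenPercentileThreshold(presSuit[!is.na(presSuit)])
  })
  current <- binarizeMap(reps@meanMap, tau)
  emit("binary_current.asc", function(p) writeAsciiGrid(current@binary, p))

  scenarios <- list()
  if (!is.null(config$scenarios)) {
    scenarios <- stage("scenarios", {
      lapply(config$scenarios, function(sc) {
        futureLayers <- prep$stack@layers
        for (nm in names(sc$shift %||% list())) {
          if (!nm %in% names(futureLayers)) next
          g <- futureLayers[[nm]]
          g@values <- g@values + sc$shift[[nm]]
          futureLayers[[nm]] <- g
        }
        if ("landcover" %in% names(futureLayers) &&
            !identical(sc$landcover, "current"))
          futureLayers$landcover <- lc$future
        projectScenario(reps, rasterStack(futureLayers), sc$label, tau,
                        current)
      })
    })
    for (s in scenarios) {
      nm <- sprintf("suitability_%s.asc", gsub("[^A-Za-z0-9._-]", "_", s@label))
      emit(nm, function(p) writeAsciiGrid(s@suitability, p))
      nmB <- sprintf("binary_%s.asc", gsub("[^A-Za-z0-9._-]", "_", s@label))
      emit(nmB, function(p) writeAsciiGrid(s@thresholded@binary, p))
    }
    emit("scenario_table.csv", function(p)
      utils::write.csv(scenarioTable(current, scenarios,
                                     cellArea = cellSize(prep$stack)^2),
                       p, row.names = FALSE))
  }

  manifest <- list(
    config = config,
    seed = seed,
    versions = list(package = as.character(utils::packageVersion("nichecast")),
                    R = R.version.string),
    selected = list(features = tune$best$features,
                    regMultiplier = tune$best$regMultiplier),
    threshold = tau,
    evaluation = list(aucTrain = evalRep$aucTrain, aucTest = evalRep$aucTest,
                      CBI = evalRep$CBI),
    rangeChange = if (length(scenarios))
      stats::setNames(lapply(scenarios, function(s) s@percentChange),
                      vapply(scenarios, function(s) s@label, character(1)))
      else NULL,
    outputs = outputs,
    wall = list(finished = format(Sys.time(), tz = "UTC"),
                elapsed = NA))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build synthetic inputs per the config's synthetic block.
.synthesizeInputs <- function(syn, seed) {
  n <- syn$nContinuous %||% 3
  cfg <- landscapeConfig(
    rows = syn$rows %||% 60, cols = syn$cols %||% 60,
    cellSize = syn$cellSize %||% 1, nContinuous = n,
    targetCorrelations = if (!is.null(syn$targetCorrelations))
      matrix(unlist(syn$targetCorrelations), n, n) else NULL,
    nLandcoverClasses = syn$nLandcoverClasses %||% 4,
    smoothing = syn$smoothing %||% 5,
    seed = .stageSeed(seed, "landscape"))
  stack <- simulatePredictors(cfg)
  tw <- syn$truth %||% list(list(kind = "L", var = "env1", weight = 3),
                            list(kind = "Q", var = "env1", weight = -2),
                            list(kind = "L", var = "env2", weight = 2))
  truth <- syntheticTruth(
    kind = vapply(tw, `[[`, character(1), "kind"),
    var = vapply(tw, `[[`, character(1), "var"),
    weight = vapply(tw, function(x) as.numeric(x$weight), numeric(1)))
  suit <- truthSuitability(stack, truth)
  occ <- samplePresences(suit, n = syn$nPresences %||% 300,
                         seed = .stageSeed(seed, "presences"))
  k <- syn$nLandcoverClasses %||% 4
  P <- if (!is.null(syn$transitionMatrix))
    matrix(unlist(syn$transitionMatrix), k, k, byrow = TRUE)
  else 0.9 * diag(k) + 0.1 / k
  spec <- transitionSpec(P / rowSums(P), classes = seq_len(k),
                         intervalYears = syn$intervalYears %||% 10)
  pair <- simulateLandcoverPair(spec, drivers = stack,
                                seed = .stageSeed(seed, "landcoverPair"))
  # the SDM's current land-cover predictor is the later map of the pair
  layers <- stack@layers
  layers$landcover <- pair$t2
  stack <- rasterStack(layers)
  list(stack = stack, occurrences = occ, truth = truth,
       landcoverT1 = pair$t1, landcoverT2 = pair$t2,
       intervalYears = spec$matrix@intervalYears)
}

.loadInputs <- function(paths) {
  preds <- paths$predictors
  layers <- lapply(preds, function(p) {
    cat <- identical(p, paths$landcover) ||
      grepl("landcover", basename(p), ignore.case = TRUE)
    readAsciiGrid(p, categorical = cat)
  })
  names(layers) <- sub("\\.asc$", "", basename(unlist(preds)))
  stack <- rasterStack(layers)
  occ <- readOccurrences(paths$occurrences)
  t1 <- readAsciiGrid(paths$landcoverT1, categorical = TRUE)
  t2 <- readAsciiGrid(paths$landcoverT2, categorical = TRUE)
  list(stack = stack, occurrences = occ, truth = NULL,
       landcoverT1 = t1, landcoverT2 = t2,
       intervalYears = paths$intervalYears %||% 10)
}
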