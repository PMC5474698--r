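## End-to-end orchestration: simulate a cohort of sessions, preprocess,
## project onto the feature space, decode per participant and per
## training-set size, and aggregate group statistics.

#' Assemble a run configuration
#'
#' Collects every knob of an end-to-end experiment with fully explicit
#' seeds. One simulated participant is one fresh session simulation seeded
#' with `sessionSeedBase + index`; classifier seeds follow the same pattern,
#' and `permutationSeedBase` (when given) enables the label-permutation null
#' with seed `permutationSeedBase + index`.
#'
#' @param cohortSize number of simulated participants
#' @param tasks decoding tasks, subset of `c("vowel", "stimulus")`
#' @param trainSizes training trials per stimulus, e.g. `950` or
#'   `seq(50, 950, 50)`
#' @param testSize test trials per stimulus (fixed 50 in the standard design)
#' @param cap artifact-free trials retained per stimulus
#' @param k feature-space dimensionality
#' @param varianceTarget optional cumulative-variance target overriding `k`
#' @param nSpeakers corpus speakers (2 vowels each)
#' @param pop a [SpeakerPopulation-class]
#' @param simCfg a [SimConfig-class] used as the per-participant template
#' @param corpusSeed,presentedSeed,sessionSeedBase,classifierSeedBase seeds
#' @param permutationSeedBase `NULL`, or base seed for label permutation
#' @return a named list of class `RunConfig`
#' @export
runConfig <- function(cohortSize = 10L, tasks = c("vowel", "stimulus"),
                      trainSizes = 950L, testSize = 50L, cap = 1000L,
                      k = 12L, varianceTarget = NULL, nSpeakers = 40L,
                      pop = speakerPopulation(), simCfg = simConfig(),
                      corpusSeed = 1L, presentedSeed = 99L,
                      sessionSeedBase = 0L, classifierSeedBase = 5000L,
                      permutationSeedBase = NULL) {
  stopifnot(cohortSize >= 1L, all(tasks %in% c("vowel", "stimulus")),
            all(trainSizes + testSize <= cap))
  structure(list(
    cohortSize = as.integer(cohortSize), tasks = tasks,
    trainSizes = as.integer(trainSizes), testSize = as.integer(testSize),
    cap = as.integer(cap), k = as.integer(k),
    varianceTarget = varianceTarget, nSpeakers = as.integer(nSpeakers),
    pop = pop, simCfg = simCfg, corpusSeed = as.integer(corpusSeed),
    presentedSeed = as.integer(presentedSeed),
    sessionSeedBase = as.integer(sessionSeedBase),
    classifierSeedBase = as.integer(classifierSeedBase),
    permutationSeedBase = permutationSeedBase), class = "RunConfig")
}

#' Preprocess one session into trial feature vectors
#'
#' The full single-participant chain: zero-phase 80-3500 Hz bandpass,
#' 310-ms epoching, baseline correction and +/-35 uV rejection, selection of
#' the first `cap` artifact-free trials per stimulus, extraction of the
#' lag-adjusted 250-ms window, spectrum computation, and projection onto the
#' feature space.
#'
#' @param rec a [ContinuousRecording-class]
#' @param space a [SpectralFeatureSpace-class]
#' @param cap artifact-free trials kept per stimulus
#' @param lag neural lag in seconds
#' @return list with `features` (trials x k), `labels`, and `counts`
#'   (per-stimulus accepted totals before capping)
#' @export
sessionFeatures <- function(rec, space, cap = 1000L, lag = 0.007) {
  es <- baselineAndReject(epochRecording(bandpassRecording(rec)))
  counts <- acceptedCounts(es)
  es <- selectTrials(es, cap = cap)
  spectra <- spectrumMatrix(analysisWindow(es, lag = lag))
  list(features = projectSpectra(space, spectra), labels = labels(es),
       counts = counts)
}

#' Decode one participant's feature vectors
#'
#' First-n/next-50 split, in-training grid search, final fit and test-set
#' evaluation for one task and one training size. With `permuteSeed` set,
#' the trial labels are randomly permuted before splitting — the
#' label-permutation null whose AUC should sit at chance.
#'
#' @param features trials x k matrix from [sessionFeatures()]
#' @param stimLabels stimulus label per trial (acquisition order)
#' @param task `"vowel"` or `"stimulus"`
#' @param trainSize training trials per stimulus
#' @param testSize test trials per stimulus
#' @param seed classifier/grid seed
#' @param permuteSeed `NULL`, or seed for the label-permutation null
#' @return list with `auc`, `perClass` (stimulus task), `hp`, `usage`
#' @export
decodeFeatures <- function(features, stimLabels, task = "vowel",
                           trainSize = 950L, testSize = 50L, seed = 1L,
                           permuteSeed = NULL) {
  stimLabels <- as.character(stimLabels)
  if (!is.null(permuteSeed)) {
    set.seed(permuteSeed)
    stimLabels <- sample(stimLabels)
  }
  sp <- splitTrials(stimLabels, trainSize, testSize)
  y <- taskLabels(stimLabels, task)
  yTr <- y[sp$train]
  yTe <- y[sp$test]
  hp <- gridSearch(features[sp$train, , drop = FALSE], yTr, seed = seed)
  clf <- trainDecoder(features[sp$train, , drop = FALSE], yTr,
                      hp$nEstimators, hp$maxDepth, seed = seed)
  probs <- predictProba(clf, features[sp$test, , drop = FALSE])
  if (task == "vowel") {
    auc <- rocAuc(probs[, clf@classes[2]], yTe == clf@classes[2])
    perClass <- NULL
  } else {
    ova <- macroOvaAuc(probs, yTe)
    auc <- ova$macro
    perClass <- ova$perClass
  }
  list(auc = auc, perClass = perClass,
       hp = list(nEstimators = hp$nEstimators, maxDepth = hp$maxDepth),
       usage = featureUsage(clf))
}

#' Run a full simulated-cohort experiment
#'
#' Fits the spectral feature space on a fresh synthetic corpus, synthesizes
#' the four presented stimuli from unseen speakers, then for each simulated
#' participant: simulates an independent session, preprocesses it, projects
#' trials into the feature space, and decodes every task at every training
#' size. Group statistics (one-sample t against chance at the largest size,
#' the logit-AUC size regression when the sweep has >= 2 sizes, and
#' feature-importance summaries) are computed from the per-participant
#' results. Deterministic given the configuration.
#'
#' @param config a [runConfig()] list
#' @param verbose print per-participant progress
#' @return list with `results` (per participant x task x size data.frame),
#'   `importances` (per task, participants x k matrix at the largest size),
#'   `group` (t tests), `regression` (per task, when applicable), `space`,
#'   `config`
#' @export
runExperiment <- function(config = runConfig(), verbose = FALSE) {
  corpus <- makeCorpus(config$pop, config$nSpeakers, seed = config$corpusSeed)
  space <- fitFeatureSpace(spectrumMatrix(corpus), k = config$k,
                           varianceTarget = config$varianceTarget)
  presented <- makePresentedSet(config$pop, seed = config$presentedSeed,
                                corpusSeed = config$corpusSeed)
  maxSize <- max(config$trainSizes)
  rows <- list()
  usage <- lapply(config$tasks, function(t) NULL)
  names(usage) <- config$tasks
  failures <- list()
  for (i in seq_len(config$cohortSize)) {
    pid <- sprintf("p%02d", i)
    res <- tryCatch({
      cfg <- config$simCfg
      cfg@seed <- config$sessionSeedBase + i
      validObject(cfg)
      rec <- simulateSession(presented, cfg)
      sf <- sessionFeatures(rec, space, cap = config$cap,
                            lag = cfg@neuralLag)
      rm(rec)
      permSeed <- if (is.null(config$permutationSeedBase)) NULL
                  else config$permutationSeedBase + i
      for (task in config$tasks) {
        for (n in config$trainSizes) {
          d <- decodeFeatures(sf$features, sf$labels, task = task,
                              trainSize = n, testSize = config$testSize,
                              seed = config$classifierSeedBase + i,
                              permuteSeed = permSeed)
          row <- data.frame(participant = pid, task = task, trainSize = n,
                            auc = d$auc, nEstimators = d$hp$nEstimators,
                            maxDepth = d$hp$maxDepth)
          if (!is.null(d$perClass))
            row <- cbind(row, as.data.frame(as.list(d$perClass)))
          rows[[length(rows) + 1L]] <- row
          if (n == maxSize)
            usage[[task]] <- rbind(usage[[task]], d$usage)
        }
      }
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(res)) {
      failures[[pid]] <- res
      warning("participant ", pid, " failed: ", res)
    } else if (verbose) {
      message("participant ", pid, " done")
    }
    gc(verbose = FALSE)
  }
  if (!length(rows)) {
    warning("no participant completed; returning an empty results table")
    return(list(results = data.frame(), importances = usage, group = list(),
                regression = list(), space = space, failures = failures,
                config = config))
  }
  allCols <- c("participant", "task", "trainSize", "auc", "nEstimators",
               "maxDepth")
  if ("stimulus" %in% config$tasks) allCols <- c(allCols, presented@labels)
  results <- do.call(function(...) rbind(..., make.row.names = FALSE),
                     lapply(rows, function(r) {
                       r[setdiff(allCols, names(r))] <- NA
                       r[, allCols, drop = FALSE]
                     }))
  group <- list()
  regression <- list()
  for (task in config$tasks) {
    atMax <- results$auc[results$task == task & results$trainSize == maxSize]
    if (length(atMax) >= 2 && var(atMax) > 0)
      group[[task]] <- oneSampleT(atMax, mu0 = 0.5)
    sub <- results[results$task == task, ]
    if (length(unique(sub$trainSize)) >= 2L)
      regression[[task]] <- sizeSweepRegression(sub)
  }
  for (task in config$tasks)
    if (!is.null(usage[[task]])) rownames(usage[[task]]) <- NULL
  list(results = results, importances = usage, group = group,
       regression = regression, space = space, failures = failures,
       config = config)
}

#' Write a small deterministic fixture bundle
#'
#' Generates, under `dir`: the four presented-stimulus WAVs with manifest, a
#' corpus manifest plus corpus spectra CSV, the fitted feature space (JSON),
#' one short simulated session's events CSV, and the expected trial feature
#' vectors CSV. Regenerating with the same seeds reproduces identical files.
#'
#' @param dir output directory
#' @param nSpeakers corpus speakers
#' @param nTrials trials per stimulus for the demo session
#' @param k feature-space dimensionality
#' @param corpusSeed,presentedSeed,sessionSeed seeds
#' @return invisibly, the list of written paths
#' @export
generateFixtures <- function(dir, nSpeakers = 40L, nTrials = 50L, k = 12L,
                             corpusSeed = 1L, presentedSeed = 99L,
                             sessionSeed = 7L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- speakerPopulation()
  corpus <- makeCorpus(pop, nSpeakers, seed = corpusSeed)
  presented <- makePresentedSet(pop, seed = presentedSeed,
                                corpusSeed = corpusSeed)
  writeStimulusSet(presented, file.path(dir, "stimuli"))
  write.csv(stimulusInfo(corpus), file.path(dir, "corpus_manifest.csv"),
            row.names = FALSE)
  spectra <- spectrumMatrix(corpus)
  space <- fitFeatureSpace(spectra, k = k)
  writeFeatureSpace(space, file.path(dir, "feature_space.json"))
  cfg <- simConfig(nTrialsPerStimulus = nTrials, seed = sessionSeed)
  rec <- simulateSession(presented, cfg)
  writeEventsCsv(rec, file.path(dir, "session_events.csv"))
  es <- baselineAndReject(epochRecording(bandpassRecording(rec)))
  keep <- acceptedTrials(es)
  w <- analysisWindow(es)[keep, , drop = FALSE]
  feats <- projectSpectra(space, spectrumMatrix(w))
  writeFeatureCsv(feats, labels(es)[keep],
                  file.path(dir, "trial_features.csv"))
  invisible(list.files(dir, recursive = TRUE, full.names = TRUE))
}
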