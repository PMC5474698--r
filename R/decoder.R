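## Gradient-boosted decision-tree decoding of trial feature vectors,
## backed by xgboost behind this module's surface. The contract is: the two
## stated objectives (binary logistic for vowels, multiclass softprob for
## stimuli), the 6 x 3 hyperparameter grid, determinism under a fixed seed,
## and tree-dump access for split-count feature importances.

#' @importFrom xgboost xgb.train xgb.DMatrix xgb.model.dt.tree xgb.dump
NULL

GRID_ESTIMATORS <- c(2L, 4L, 6L, 8L, 10L, 12L)
GRID_DEPTH <- c(2L, 4L, 6L)

#' First-n / next-50 train-test split
#'
#' Per stimulus, the training set is the first `trainSize` trials in
#' acquisition order and the test set is the `testSize` trials that
#' immediately follow — never shuffled, so training and test sets are
#' disjoint and temporally ordered.
#'
#' @param stimLabels stimulus label per trial, in acquisition order
#' @param trainSize training trials per stimulus (50..950 in the standard
#'   sweep)
#' @param testSize test trials per stimulus (fixed at 50)
#' @return list with integer index vectors `train` and `test`
#' @export
splitTrials <- function(stimLabels, trainSize, testSize = 50L) {
  train <- integer(0)
  test <- integer(0)
  for (lab in unique(stimLabels)) {
    idx <- which(stimLabels == lab)
    if (length(idx) < trainSize + testSize)
      stop("stimulus ", lab, ": ", length(idx), " trials, need ",
           trainSize + testSize)
    train <- c(train, idx[seq_len(trainSize)])
    test <- c(test, idx[trainSize + seq_len(testSize)])
  }
  list(train = sort(train), test = sort(test))
}

taskLabels <- function(stimLabels, task) {
  if (task == "vowel") vowelOf(stimLabels) else stimLabels
}

fitBooster <- function(x, y01, objective, nClass, nEstimators, maxDepth,
                       eta, seed) {
  params <- list(objective = objective, max_depth = maxDepth, eta = eta,
                 nthread = 1, seed = seed)
  if (objective == "multi:softprob") params$num_class <- nClass
  dtrain <- xgb.DMatrix(x, label = y01, nthread = 1)
  xgb.train(params = params, data = dtrain, nrounds = nEstimators,
            verbose = 0)
}

#' Train a gradient-boosted tree decoder
#'
#' Binary logistic objective for the 2-class vowel task, multiclass
#' probability (softprob) for the 4-class stimulus task. Single-threaded and
#' seeded, so training is deterministic.
#'
#' @param x n x k feature matrix (columns `pc1..pck`)
#' @param y labels: vowels (`ae`/`u`) or stimulus labels
#' @param nEstimators number of boosting rounds (grid: 2-12 step 2)
#' @param maxDepth maximum tree depth (grid: 2-6 step 2)
#' @param eta learning rate (default 0.3, the backend default)
#' @param seed training seed
#' @return an [FFRClassifier-class]
#' @export
trainDecoder <- function(x, y, nEstimators, maxDepth, eta = 0.3, seed = 1L) {
  classes <- sort(unique(as.character(y)))
  if (!length(classes) %in% c(2L, 4L))
    stop("expected 2 (vowel) or 4 (stimulus) classes, got ", length(classes))
  if (is.null(colnames(x))) colnames(x) <- paste0("pc", seq_len(ncol(x)))
  task <- if (length(classes) == 2L) "vowel" else "stimulus"
  objective <- if (task == "vowel") "binary:logistic" else "multi:softprob"
  y01 <- match(as.character(y), classes) - 1L
  booster <- fitBooster(x, y01, objective, length(classes),
                        as.integer(nEstimators), as.integer(maxDepth), eta,
                        as.integer(seed))
  new("FFRClassifier", booster = booster, classes = classes, task = task,
      nEstimators = as.integer(nEstimators), maxDepth = as.integer(maxDepth),
      eta = eta, k = ncol(x), seed = as.integer(seed))
}

#' Predicted class probabilities
#'
#' @param clf an [FFRClassifier-class]
#' @param x n x k feature matrix
#' @return n x C probability matrix (rows sum to 1), columns named by class
#' @export
predictProba <- function(clf, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != clf@k)
    stop("feature length ", ncol(x), " does not match classifier k = ",
         clf@k)
  if (is.null(colnames(x))) colnames(x) <- paste0("pc", seq_len(ncol(x)))
  p <- predict(clf@booster, xgb.DMatrix(x, nthread = 1))
  if (length(clf@classes) == 2L) {
    p <- cbind(1 - p, p)               # p is P(second class)
  }
  colnames(p) <- clf@classes
  p
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates all 18 cells of the grid (estimators 2-12 step 2, depth 2-6
#' step 2) by stratified `nFolds`-fold cross-validation within the training
#' set, scoring mean held-out AUC (binary AUC for the vowel task, macro
#' one-vs-all for the stimulus task). Ties are broken toward fewer
#' estimators, then smaller depth.
#'
#' @param x n x k training feature matrix
#' @param y training labels (2 or 4 classes, all present)
#' @param seed seed controlling fold assignment and training
#' @param nFolds cross-validation folds (default 3)
#' @param eta learning rate passed to training
#' @return list with `nEstimators`, `maxDepth`, `score`, and the full `grid`
#'   data.frame of cell scores
#' @export
gridSearch <- function(x, y, seed = 1L, nFolds = 3L, eta = 0.3) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (!length(classes) %in% c(2L, 4L))
    stop("expected 2 or 4 classes in the training labels")
  if (min(table(y)) < nFolds)
    stop("every class needs at least ", nFolds, " training trials")
  folds <- stratifiedFolds(y, nFolds, seed)
  grid <- expand.grid(nEstimators = GRID_ESTIMATORS, maxDepth = GRID_DEPTH,
                      KEEP.OUT.ATTRS = FALSE)
  ## enumerate so that earlier rows are preferred on ties
  grid <- grid[order(grid$nEstimators, grid$maxDepth), ]
  grid$score <- vapply(seq_len(nrow(grid)), function(g) {
    sc <- vapply(seq_len(nFolds), function(f) {
      tr <- folds != f
      clf <- trainDecoder(x[tr, , drop = FALSE], y[tr],
                          grid$nEstimators[g], grid$maxDepth[g],
                          eta = eta, seed = seed)
      probs <- predictProba(clf, x[!tr, , drop = FALSE])
      scoreAuc(probs, y[!tr], classes)
    }, numeric(1))
    mean(sc)
  }, numeric(1))
  best <- which(grid$score >= max(grid$score) - 1e-12)[1]
  list(nEstimators = grid$nEstimators[best], maxDepth = grid$maxDepth[best],
       score = grid$score[best], grid = grid)
}

stratifiedFolds <- function(y, nFolds, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep(seq_len(nFolds), length.out = length(idx))
  }
  folds
}

scoreAuc <- function(probs, yTrue, classes) {
  if (length(classes) == 2L)
    rocAuc(probs[, classes[2]], yTrue == classes[2])
  else
    macroOvaAuc(probs, yTrue)$macro
}

#' Split-count feature importances
#'
#' For each of the k spectral features, the percentage of split nodes across
#' all trees of the ensemble that test that feature. Percentages sum to 100
#' whenever the ensemble contains any split; an all-stump ensemble (no
#' splits) yields zeros with a warning.
#'
#' @param clf an [FFRClassifier-class]
#' @return named numeric vector of k percentages
#' @export
featureUsage <- function(clf) {
  feats <- paste0("pc", seq_len(clf@k))
  tab <- as.data.frame(xgb.model.dt.tree(model = clf@booster))
  splits <- tab$Feature[tab$Feature != "Leaf"]
  if (!length(splits)) {
    warning("ensemble contains no split nodes; all importances zero")
    out <- numeric(clf@k)
    names(out) <- feats
    return(out)
  }
  counts <- table(factor(splits, levels = feats))
  out <- 100 * as.numeric(counts) / length(splits)
  names(out) <- feats
  out
}

#' Plain-text dump of the fitted ensemble
#'
#' Exposes the backend's tree dump (one line per node) for inspection and
#' independent verification of [featureUsage()].
#'
#' @param clf an [FFRClassifier-class]
#' @return character vector of dump lines
#' @export
dumpTrees <- function(clf) xgb.dump(clf@booster)
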