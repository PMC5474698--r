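#' Binary ROC AUC
#'
#' Rank-based AUC: the probability that a randomly chosen positive scores
#' above a randomly chosen negative, with ties counted half — identical to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric classifier scores (higher = more positive)
#' @param labels logical (TRUE = positive) or two-level vector; for a
#'   two-level factor/character the second sorted level is the positive class
#' @return AUC in \[0, 1\]
#' @examples
#' rocAuc(c(.9, .8, .3, .2), c(TRUE, TRUE, FALSE, FALSE))  # 1
#' @export
rocAuc <- function(scores, labels) {
  if (!is.logical(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2L)
      stop("labels must have exactly two levels, got ", length(lv))
    labels <- as.character(labels) == lv[2]
  }
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Macro one-vs-all AUC
#'
#' For each class, a binary AUC of that class's predicted probability
#' against class membership; the macro AUC is their unweighted mean (chance
#' 0.5). Averaging one-vs-all curves avoids accuracy inflation from a
#' response-biased classifier.
#'
#' @param probs n x C probability matrix with class column names
#' @param labels true class per row; every class must occur
#' @return list with `perClass` (named AUCs) and `macro`
#' @export
macroOvaAuc <- function(probs, labels) {
  classes <- colnames(probs)
  if (is.null(classes)) stop("probability matrix must have class colnames")
  labels <- as.character(labels)
  missing <- setdiff(classes, labels)
  if (length(missing))
    stop("class(es) absent from labels: ", paste(missing, collapse = ", "))
  per <- vapply(classes, function(cl) rocAuc(probs[, cl], labels == cl),
                numeric(1))
  list(perClass = per, macro = mean(per))
}

#' Logit transform of an AUC
#'
#' `ln(x / (1 - x))` after clipping into `[eps, 1 - eps]`, so 0.5 maps to 0
#' exactly and perfect scores stay finite.
#'
#' @param x fractions in \[0, 1\]
#' @param eps clipping bound (default 0.001)
#' @return logit values
#' @export
logitAuc <- function(x, eps = 0.001) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("values must lie in [0, 1]")
  x <- pmin(pmax(x, eps), 1 - eps)
  log(x / (1 - x))
}

#' One-sample t test against a reference value
#'
#' Two-sided test of the mean against `mu0` (chance = 0.5 for AUCs), with
#' the 95% confidence interval of the mean.
#'
#' @param values numeric sample (n >= 2, non-constant)
#' @param mu0 null mean
#' @return list with `t`, `df`, `p`, `ci95`, `mean`, `sd`
#' @export
oneSampleT <- function(values, mu0 = 0.5) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (var(values) == 0) stop("zero-variance sample: t is undefined")
  ht <- t.test(values, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, ci95 = unname(ht$conf.int), mean = mean(values),
       sd = sd(values))
}

#' Regression of logit-AUC on training-set size
#'
#' Ordinary least squares of logit-transformed AUC on training trials per
#' stimulus, pooled over participants, with the predictor centered at the
#' smallest size (default 50) so the intercept is the expected logit-AUC at
#' that size. Participant-clustered standard errors are available when the
#' `sandwich` package is installed.
#'
#' @param results data.frame with columns `participant`, `trainSize`, `auc`
#' @param center size at which the intercept is anchored (default 50)
#' @param clusterSE use participant-clustered (CR0) standard errors
#' @return list with `coefficients` (data.frame: term, estimate, se, t, p),
#'   `nObs`, and the fitted `model`
#' @export
sizeSweepRegression <- function(results, center = 50, clusterSE = FALSE) {
  if (length(unique(results$trainSize)) < 2L)
    stop("need at least 2 distinct training sizes")
  df <- data.frame(y = logitAuc(results$auc),
                   size = results$trainSize - center,
                   participant = results$participant)
  fit <- lm(y ~ size, data = df)
  vc <- if (clusterSE) {
    if (!requireNamespace("sandwich", quietly = TRUE))
      stop("clustered SEs require the 'sandwich' package")
    sandwich::vcovCL(fit, cluster = df$participant)
  } else vcov(fit)
  est <- coef(fit)
  se <- sqrt(diag(vc))
  tval <- est / se
  dfRes <- fit$df.residual
  pval <- 2 * pt(-abs(tval), dfRes)
  list(coefficients = data.frame(
         term = c("intercept", "slope"), estimate = unname(est),
         se = unname(se), t = unname(tval), p = unname(pval)),
       nObs = nrow(df), model = fit)
}

#' Distribution of feature weights across participants
#'
#' Per-feature mean, SD and median of split-count importances (percent) over
#' a cohort.
#'
#' @param weights participants x k matrix of percentages (rows sum to 100)
#' @return data.frame with columns feature, mean, sd, median
#' @export
summarizeImportances <- function(weights) {
  if (is.null(dim(weights))) weights <- matrix(weights, 1)
  k <- ncol(weights)
  feats <- colnames(weights)
  if (is.null(feats)) feats <- paste0("pc", seq_len(k))
  data.frame(feature = feats,
             mean = apply(weights, 2, mean),
             sd = apply(weights, 2, sd),
             median = apply(weights, 2, median),
             row.names = NULL)
}

#' Spectral extrema of a principal component
#'
#' Local extrema (maxima and minima) of one component's 1,000-bin curve
#' whose absolute value reaches `prominence` times the component's maximum
#' absolute value, sorted by frequency. For a feature space fitted to a
#' vowel corpus, the extrema of the top vowel-discriminative component fall
#' at the formant frequencies that separate the vowels.
#'
#' @param space a [SpectralFeatureSpace-class]
#' @param component component index (default 1)
#' @param prominence height threshold as a fraction of `max(abs(value))`
#' @return data.frame with columns `freqHz`, `value`
#' @export
pcExtrema <- function(space, component = 1L, prominence = 0.2) {
  v <- space@components[component, ]
  n <- length(v)
  thr <- prominence * max(abs(v)) * (1 - 1e-12)
  inner <- 2:(n - 1)
  isMax <- v[inner] > v[inner - 1] & v[inner] >= v[inner + 1] &
    v[inner] >= thr
  isMin <- v[inner] < v[inner - 1] & v[inner] <= v[inner + 1] &
    -v[inner] >= thr
  idx <- inner[isMax | isMin]
  data.frame(freqHz = binFrequencies()[idx], value = unname(v[idx]))
}
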