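#' Fit the PCA spectral feature space
#'
#' Mean-centered principal component analysis (covariance PCA, no per-bin
#' scaling) of the corpus log-magnitude spectra. Components are
#' variance-ordered, orthonormal, and sign-fixed so that each component's
#' largest-magnitude element is positive. Either a fixed number of components
#' `k` (default 12) or a cumulative explained-variance target may be
#' requested; with a target, the smallest `k` whose cumulative ratio reaches
#' it is kept.
#'
#' @param spectra n x 1000 matrix of corpus spectra (rows = sounds)
#' @param k number of components to retain (ignored when `varianceTarget`
#'   is given)
#' @param varianceTarget fraction in (0, 1\]: retain the smallest number of
#'   components whose cumulative explained-variance ratio reaches it
#' @return a [SpectralFeatureSpace-class]
#' @examples
#' \donttest{
#' corpus <- makeCorpus(speakerPopulation(), nSpeakers = 10, seed = 1)
#' fs <- fitFeatureSpace(spectrumMatrix(corpus), k = 5)
#' cumulativeVariance(fs)[5]
#' }
#' @export
fitFeatureSpace <- function(spectra, k = 12L, varianceTarget = NULL) {
  if (nrow(spectra) < 2L) stop("need at least 2 corpus spectra")
  ctr <- unname(colMeans(spectra))
  xc <- sweep(spectra, 2, ctr)
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank == 0L) stop("zero-variance corpus: no principal components exist")
  ev <- sv$d[seq_len(rank)]^2 / (nrow(spectra) - 1)   # eigenvalues of cov
  ratios <- ev / sum(ev)
  if (!is.null(varianceTarget)) {
    if (varianceTarget <= 0 || varianceTarget > 1)
      stop("varianceTarget must be in (0, 1]")
    k <- which(cumsum(ratios) >= varianceTarget - 1e-12)[1]
    if (is.na(k)) k <- rank
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > rank)
    stop("k = ", k, " exceeds the achievable rank ", rank,
         " of the corpus spectra")
  comp <- t(sv$v[, seq_len(k), drop = FALSE])
  ## deterministic sign: largest-|.| element of each component positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  rownames(comp) <- paste0("pc", seq_len(k))
  new("SpectralFeatureSpace", center = ctr, components = comp,
      varianceRatio = ratios[seq_len(k)], allVarianceRatio = ratios,
      k = k)
}

#' Project spectra onto the feature space
#'
#' Centers each spectrum with the corpus mean and takes its coordinates
#' along the k principal spectral components:
#' `weights = components %*% (s - center)`. Each single-trial FFR spectrum
#' thus becomes a k-vector of spectral-feature weights (k = 12 in the
#' standard analysis). FFR spectra receive the identical transform as corpus
#' spectra; centering always uses the corpus mean, keeping the projection an
#' affine map independent of the neural data.
#'
#' @param space a [SpectralFeatureSpace-class]
#' @param spectra a single 1,000-bin spectrum or an n x 1000 matrix
#' @return n x k matrix of projection weights (columns `pc1..pck`)
#' @export
projectSpectra <- function(space, spectra) {
  if (is.null(dim(spectra))) spectra <- matrix(spectra, 1)
  if (ncol(spectra) != length(space@center))
    stop("spectra have ", ncol(spectra), " bins; feature space expects ",
         length(space@center))
  w <- sweep(spectra, 2, space@center) %*% t(space@components)
  colnames(w) <- rownames(space@components)
  w
}

#' Reconstruct spectra from projection weights
#'
#' Inverse of [projectSpectra()] restricted to the retained subspace:
#' `center + weights %*% components`.
#'
#' @param space a [SpectralFeatureSpace-class]
#' @param weights n x k weight matrix (or k-vector)
#' @return n x 1000 matrix of reconstructed spectra
#' @export
reconstructSpectra <- function(space, weights) {
  if (is.null(dim(weights))) weights <- matrix(weights, 1)
  if (ncol(weights) != space@k)
    stop("weights have ", ncol(weights), " columns; feature space has k = ",
         space@k)
  sweep(weights %*% space@components, 2, space@center, "+")
}

#' Cumulative explained variance
#'
#' Running sum of the explained-variance ratios over the full decomposition;
#' non-decreasing, ending at 1.
#'
#' @param space a [SpectralFeatureSpace-class]
#' @return numeric vector of cumulative fractions
#' @export
cumulativeVariance <- function(space) cumsum(space@allVarianceRatio)

#' Serialize a feature space to a JSON file
#'
#' Stores mean, components, ratios and k in a single portable text file.
#'
#' @param space a [SpectralFeatureSpace-class]
#' @param path output path
#' @return invisibly, `path`
#' @export
writeFeatureSpace <- function(space, path) {
  obj <- list(center = space@center,
              components = unname(space@components),
              varianceRatio = space@varianceRatio,
              allVarianceRatio = space@allVarianceRatio,
              k = space@k)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature space written by writeFeatureSpace
#'
#' @param path JSON file produced by [writeFeatureSpace()]
#' @return a [SpectralFeatureSpace-class]
#' @export
readFeatureSpace <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- obj$components
  rownames(comp) <- paste0("pc", seq_len(obj$k))
  new("SpectralFeatureSpace", center = obj$center, components = comp,
      varianceRatio = obj$varianceRatio,
      allVarianceRatio = obj$allVarianceRatio, k = as.integer(obj$k))
}

#' Export trial feature vectors as CSV
#'
#' @param weights n x k matrix from [projectSpectra()]
#' @param labels stimulus label per trial
#' @param path output CSV path
#' @return invisibly, the written data.frame
#' @export
writeFeatureCsv <- function(weights, labels, path) {
  df <- data.frame(trial_id = seq_len(nrow(weights)),
                   stimulus_label = labels, weights, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
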