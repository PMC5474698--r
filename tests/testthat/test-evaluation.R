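test_that("binary AUC handles perfect ranking, ties, and the pairwise oracle", {
  expect_equal(rocAuc(c(.9, .8, .3, .2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  # 6 scores with one tie: brute-force average over all (pos, neg) pairs
  s <- c(.9, .7, .7, .4, .3, .1)
  l <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(rocAuc(s, l), pairwiseAuc(s, l))
  expect_error(rocAuc(1:5, rep(TRUE, 5)), "both classes")
  expect_error(rocAuc(1:5, c("a", "b", "c", "a", "b")), "two levels")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.4, .6))
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(n, mean = lab), 1)   # rounding forces ties
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(sc, lab), ref, tolerance = 1e-12)
  }
})

test_that("AUC complement identity holds for tie-free scores", {
  set.seed(15)
  sc <- rnorm(20)
  lab <- rep(c(TRUE, FALSE), 10)
  expect_equal(rocAuc(sc, lab) + rocAuc(-sc, lab), 1)
})

test_that("macro one-vs-all AUC averages per-class binary AUCs", {
  classes <- c("ae1", "u1", "ae2", "u2")
  set.seed(16)
  lab <- sample(rep(classes, 10))
  # one-hot probabilities: perfect per-class and macro AUC
  onehot <- outer(lab, classes, "==") * 1
  colnames(onehot) <- classes
  ova <- macroOvaAuc(onehot, lab)
  expect_equal(unname(ova$perClass), rep(1, 4))
  expect_equal(ova$macro, 1)

  uniform <- matrix(0.25, 40, 4, dimnames = list(NULL, classes))
  expect_equal(macroOvaAuc(uniform, lab)$macro, 0.5)

  probs <- matrix(runif(160), 40, 4, dimnames = list(NULL, classes))
  probs <- probs / rowSums(probs)
  ova2 <- macroOvaAuc(probs, lab)
  per <- vapply(classes, function(cl) rocAuc(probs[, cl], lab == cl),
                numeric(1))
  expect_equal(ova2$perClass, per)
  expect_equal(ova2$macro, mean(per))
  # invariant to class re-ordering
  perm <- c(3, 1, 4, 2)
  expect_equal(macroOvaAuc(probs[, perm], lab)$macro, ova2$macro)
  expect_error(macroOvaAuc(probs, rep("ae1", 40)), "absent")
})

test_that("the logit transform maps chance to zero and clips extremes", {
  expect_identical(logitAuc(0.5), 0)
  expect_equal(logitAuc(1), log(0.999 / 0.001))
  expect_equal(logitAuc(0), -log(0.999 / 0.001))
  expect_equal(logitAuc(0.75), log(3))
  expect_error(logitAuc(1.2), "0, 1|\\[0, 1\\]")
})

test_that("the one-sample t test matches the textbook formula", {
  set.seed(17)
  x <- round(rnorm(10, 0.6, 0.1), 3)
  res <- oneSampleT(x, mu0 = 0.5)
  expect_equal(res$df, 9)
  tOracle <- (mean(x) - 0.5) / (sd(x) / sqrt(10))
  expect_equal(res$t, tOracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(tOracle), 9), tolerance = 1e-12)

  res25 <- oneSampleT(rnorm(25, 0.6, 0.1), 0.5)
  expect_equal(res25$df, 24)

  nearConst <- rep(0.6, 8) + c(rep(0, 7), 1e-9)
  expect_gt(oneSampleT(nearConst, 0.5)$t, 1e5)
  expect_error(oneSampleT(rep(0.5, 5), 0.5), "variance")
  expect_error(oneSampleT(0.7, 0.5), "2")
})

test_that("the size regression is anchored at 50 trials and recovers slopes", {
  sizes <- seq(50, 950, 50)
  # all AUCs at chance: intercept and slope are exactly zero
  flat <- data.frame(participant = rep("p1", 19), trainSize = sizes,
                     auc = 0.5)
  rFlat <- sizeSweepRegression(flat)
  expect_equal(rFlat$coefficients$estimate, c(0, 0), tolerance = 1e-12)

  # data generated from a known logit-linear model: slope within 2 SE
  b0 <- 0.8; b1 <- 0.001
  set.seed(21)
  sim <- do.call(rbind, lapply(1:12, function(p) {
    eta <- b0 + b1 * (sizes - 50) + rnorm(19, 0, 0.15)
    data.frame(participant = sprintf("p%02d", p), trainSize = sizes,
               auc = 1 / (1 + exp(-eta)))
  }))
  r <- sizeSweepRegression(sim)
  slope <- r$coefficients[r$coefficients$term == "slope", ]
  expect_lt(abs(slope$estimate - b1), 2 * slope$se)
  intercept <- r$coefficients[r$coefficients$term == "intercept", ]
  expect_lt(abs(intercept$estimate - b0), 4 * intercept$se)
  # t = estimate / SE for both coefficients
  expect_equal(r$coefficients$t,
               r$coefficients$estimate / r$coefficients$se,
               tolerance = 1e-12)
  expect_equal(r$nObs, 12 * 19)
  expect_error(sizeSweepRegression(flat[1, ]), "distinct")
})

test_that("clustered standard errors are available and larger-or-equal here", {
  skip_if_not_installed("sandwich")
  sizes <- seq(50, 950, 100)
  set.seed(19)
  sim <- do.call(rbind, lapply(1:8, function(p) {
    off <- rnorm(1, 0, 0.4)   # participant-level shift induces clustering
    data.frame(participant = p, trainSize = sizes,
               auc = 1 / (1 + exp(-(0.5 + off + rnorm(10, 0, 0.05)))))
  }))
  plain <- sizeSweepRegression(sim)
  clus <- sizeSweepRegression(sim, clusterSE = TRUE)
  expect_equal(clus$coefficients$estimate, plain$coefficients$estimate)
  expect_false(identical(clus$coefficients$se, plain$coefficients$se))
})

test_that("importance summaries reduce to hand-computed statistics", {
  all1 <- matrix(c(100, 0, 0), 3, 3, byrow = TRUE,
                 dimnames = list(NULL, paste0("pc", 1:3)))
  s1 <- summarizeImportances(all1)
  expect_equal(s1$mean, c(100, 0, 0))
  expect_equal(s1$sd, c(0, 0, 0))

  w <- rbind(c(60, 30, 10), c(40, 40, 20), c(20, 50, 30))
  colnames(w) <- paste0("pc", 1:3)
  s <- summarizeImportances(w)
  expect_equal(s$mean, c(40, 40, 20))
  expect_equal(s$median, c(40, 40, 20))
  expect_equal(s$sd, c(20, 10, 10))
  # rows sum to 100, so per-feature means sum to 100
  expect_equal(sum(s$mean), 100)
})

test_that("component extrema localize constructed and fitted features", {
  # single Gaussian bump at 600 Hz: exactly one extremum, within one bin
  grid <- binFrequencies()
  bump <- exp(-(grid - 600)^2 / (2 * 50^2))
  bump <- bump / sqrt(sum(bump^2))
  ortho <- rep(1 / sqrt(1000), 1000) -
    sum(rep(1 / sqrt(1000), 1000) * bump) * bump
  ortho <- ortho / sqrt(sum(ortho^2))
  space <- new("SpectralFeatureSpace", center = rep(0, 1000),
               components = rbind(bump, ortho), varianceRatio = c(.7, .3),
               allVarianceRatio = c(.7, .3), k = 2L)
  ex <- pcExtrema(space, 1, prominence = 0.2)
  expect_equal(nrow(ex), 1L)
  expect_lte(abs(ex$freqHz - 600), 4)
  # prominence 100%: at most one extremum survives
  expect_lte(nrow(pcExtrema(space, 1, prominence = 1)), 1L)

  # corpus with a pure [ae]/[u] formant contrast (f0 varies, formants do
  # not): the vowel-discriminative component localizes the [ae] formants at
  # harmonic resolution (the envelope is only sampled every f0 Hz)
  popC <- speakerPopulation(formantSds = c(0, 0, 0))
  corpusC <- makeCorpus(popC, nSpeakers = 40, seed = 1)
  spC <- spectrumMatrix(corpusC)
  spaceC <- fitFeatureSpace(spC, k = 12)
  w <- projectSpectra(spaceC, spC)
  v <- vowelOf(labels(corpusC))
  tstat <- vapply(1:12, function(j)
    abs(t.test(w[v == "ae", j], w[v == "u", j])$statistic), numeric(1))
  best <- which.max(tstat)
  ex2 <- pcExtrema(spaceC, best, prominence = 0.2)
  comp <- spectralComponents(spaceC)[best, ]
  # smooth at the harmonic scale (~125 Hz = 31 bins): the component energy
  # concentrates within half a harmonic spacing of each [ae] formant
  sm <- as.numeric(stats::filter(abs(comp), rep(1 / 31, 31), sides = 2))
  for (f in c(650, 1850, 2550)) {
    win <- which(abs(grid - f) <= 200 & !is.na(sm))
    peak <- grid[win[which.max(sm[win])]]
    expect_lte(abs(peak - f), 62.5)
    # and pcExtrema reports an extremum in the same neighbourhood
    expect_lte(min(abs(ex2$freqHz - f)), 62.5)
  }
})
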