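#' Global-rank AUC (Mann-Whitney form)
#'
#' The probability that a test score outranks a candidate score, with ties
#' credited 0.5: the mean over all (test, candidate) pairs of
#' 1 (test higher), 0.5 (equal) or 0. Computed via midranks in
#' O((|T|+|C|) log(|T|+|C|)); identical to the trapezoidal area under the
#' threshold-swept ROC curve.
#'
#' @param testScores numeric vector of held-out true-association scores.
#' @param candidateScores numeric vector of never-known pair scores.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' globalRankAuc(0.9, c(0.1, 0.5))  # 1
#' globalRankAuc(0.3, c(0.1, 0.5))  # 0.5
globalRankAuc <- function(testScores, candidateScores) {
  nt <- length(testScores)
  nc <- length(candidateScores)
  stopIfNot(nt >= 1L && nc >= 1L, "both score lists must be non-empty")
  stopIfNot(all(is.finite(testScores)) && all(is.finite(candidateScores)),
            "scores must be finite")
  r <- rank(c(testScores, candidateScores))  # midranks handle ties as 0.5
  (sum(r[seq_len(nt)]) - nt * (nt + 1) / 2) / (nt * nc)
}

# Ordered (FPR, TPR) points from a threshold sweep over the pooled scores,
# running from (0,0) to (1,1).
rocPoints <- function(testScores, candidateScores) {
  u <- sort(unique(c(testScores, candidateScores)), decreasing = TRUE)
  tpr <- cumsum(tabulate(match(testScores, u), nbins = length(u))) / length(testScores)
  fpr <- cumsum(tabulate(match(candidateScores, u), nbins = length(u))) / length(candidateScores)
  unname(rbind(c(0, 0), cbind(fpr, tpr)))
}

# Default fold scorer: rebuild similarities from the masked association
# matrix (or reuse prebuilt ones) and run the scoring pipeline.
.makeDefaultScorer <- function(assoc, fs, corpus, config) {
  sem <- buildSemanticMatrices(corpus, config@delta, diseaseNames(assoc))
  prebuilt <- NULL
  if (!config@recomputeKernels) {
    km <- mirnaKernel(assoc, config@gammaM)
    kd <- diseaseKernel(assoc, config@gammaD)
    prebuilt <- list(sm = integrateMirnaSimilarity(fs, km),
                     sd = integrateDiseaseSimilarity(sem$ss1, sem$ss2, kd, sem$mask))
  }
  function(masked) {
    sims <- if (is.null(prebuilt)) {
      km <- mirnaKernel(masked, config@gammaM)
      kd <- diseaseKernel(masked, config@gammaD)
      list(sm = integrateMirnaSimilarity(fs, km),
           sd = integrateDiseaseSimilarity(sem$ss1, sem$ss2, kd, sem$mask))
    } else prebuilt
    grmdaScore(masked, sims$sm, sims$sd, config)
  }
}

# Shared CV engine: mask each fold's known cells, score, and rate each test
# cell against that fold's candidate (never-known) scores.
.runFolds <- function(a, folds, scorer, candIdx) {
  cellAucs <- numeric(0)
  testPool <- numeric(0)
  candPool <- numeric(0)
  for (fold in folds) {
    masked <- a
    masked[fold] <- 0
    c <- as.matrix(scorer(AssociationMatrix(masked)))
    candScores <- c[candIdx]
    testScores <- c[fold]
    cellAucs <- c(cellAucs,
                  vapply(testScores, globalRankAuc, numeric(1), candScores))
    testPool <- c(testPool, testScores)
    candPool <- c(candPool, candScores)
  }
  list(cellAucs = cellAucs, testPool = testPool, candPool = candPool)
}

#' Leave-one-out cross validation
#'
#' Each known association is masked in turn; the pipeline rescores the
#' matrix (by default rebuilding the Gaussian kernels from the masked
#' matrix, so the held-out association cannot leak into the similarity
#' graphs), and the held-out cell's score is ranked against the scores of
#' all never-known pairs from the same fold. The reported AUC pools all
#' folds in the Mann-Whitney form; the ROC curve is a threshold sweep over
#' the pooled test and candidate scores.
#'
#' @param assoc an [AssociationMatrix] with at least one known association.
#' @param fs functional [SimilarityMatrix] over the miRNA axis.
#' @param corpus a [DagCorpus].
#' @param config a [GrmdaConfig]; its seed drives the subsample draw.
#' @param maxFolds optional cap: evaluate a seeded random subsample of this
#'   many known associations instead of all of them.
#' @param scorer optional override, a \code{function(maskedAssoc)} returning
#'   a [ScoreMatrix]; replaces the whole similarity + scoring stage (used
#'   for protocol tests and method comparisons).
#' @return a [CvResult] (one repetition; \code{aucSd} = 0).
#' @export
loocv <- function(assoc, fs, corpus, config = grmdaConfig(),
                  maxFolds = NULL, scorer = NULL) {
  a <- as.matrix(assoc)
  known <- which(a == 1)
  stopIfNot(length(known) >= 1L, "no known associations to cross-validate")
  candIdx <- which(a == 0)
  stopIfNot(length(candIdx) >= 1L, "no candidate (unknown) pairs")
  if (!is.null(maxFolds) && maxFolds < length(known)) {
    known <- withSeed(config@seed, sample(known, maxFolds))
  }
  if (is.null(scorer)) scorer <- .makeDefaultScorer(assoc, fs, corpus, config)
  res <- .runFolds(a, as.list(known), scorer, candIdx)
  auc <- mean(res$cellAucs)
  new("CvResult", auc = auc, aucSd = 0, perRepAucs = auc,
      rocPoints = rocPoints(res$testPool, res$candPool),
      nFolds = length(known), seed = config@seed)
}

# Seeded partition of indices into k near-equal folds: the first
# (n mod k) folds receive one extra element.
.partitionFolds <- function(idx, k) {
  n <- length(idx)
  perm <- sample(idx)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(perm, rep(seq_len(k), times = sizes))
}

#' Repeated k-fold cross validation
#'
#' Per repetition, the known associations are randomly partitioned into k
#' near-equal parts; each part is masked in turn and its cells are scored
#' against the never-known pairs, yielding one pooled AUC per repetition
#' (all k folds jointly). The mean and standard deviation over repetitions
#' are reported. Seeded and reproducible via the configuration seed.
#'
#' @inheritParams loocv
#' @param k number of folds (default 5).
#' @param reps number of repetitions (default 100).
#' @return a [CvResult] with \code{perRepAucs} of length \code{reps}; the
#'   ROC curve is built from the final repetition's pooled scores.
#' @export
kfoldCv <- function(assoc, fs, corpus, config = grmdaConfig(),
                    k = 5, reps = 100, scorer = NULL) {
  a <- as.matrix(assoc)
  known <- which(a == 1)
  stopIfNot(k >= 2L, "k must be at least 2")
  stopIfNot(length(known) >= k, "fewer known associations than folds")
  candIdx <- which(a == 0)
  stopIfNot(length(candIdx) >= 1L, "no candidate (unknown) pairs")
  if (is.null(scorer)) scorer <- .makeDefaultScorer(assoc, fs, corpus, config)
  repAucs <- numeric(reps)
  lastRes <- NULL
  withSeed(config@seed, {
    for (rep in seq_len(reps)) {
      folds <- .partitionFolds(known, k)
      res <- .runFolds(a, folds, scorer, candIdx)
      repAucs[rep] <- mean(res$cellAucs)
      if (rep == reps) lastRes <- res
    }
  })
  new("CvResult", auc = mean(repAucs),
      aucSd = if (reps > 1) stats::sd(repAucs) else 0,
      perRepAucs = repAucs,
      rocPoints = rocPoints(lastRes$testPool, lastRes$candPool),
      nFolds = as.integer(k), seed = config@seed)
}

#' Zero out a disease's association column (new-disease mode)
#'
#' Returns a copy of the association matrix in which the given disease has
#' no known associations, emulating a new disease; the input is unchanged.
#'
#' @param assoc an [AssociationMatrix].
#' @param disease a disease label present in the matrix.
#' @return an [AssociationMatrix].
#' @export
zeroDiseaseColumn <- function(assoc, disease) {
  a <- as.matrix(assoc)
  stopIfNot(disease %in% colnames(a), "unknown disease label: ", disease)
  a[, disease] <- 0
  AssociationMatrix(a)
}

#' Ranked candidate miRNAs for one disease
#'
#' Sorts the disease's column of the score matrix in descending order (ties
#' broken by miRNA label for determinism) and returns the top entries.
#' Known-associated miRNAs are excluded from the candidate list by default.
#'
#' @param scores a [ScoreMatrix].
#' @param assoc the [AssociationMatrix] defining which pairs are known.
#' @param disease a disease label.
#' @param excludeKnown drop miRNAs already associated with the disease.
#' @param topK list length (default 50).
#' @return data.frame with columns \code{mirna}, \code{score}, \code{rank}.
#' @export
rankForDisease <- function(scores, assoc, disease, excludeKnown = TRUE,
                           topK = 50) {
  s <- as.matrix(scores)
  a <- as.matrix(assoc)
  checkSameLabels(rownames(s), rownames(a), "scores/association miRNA")
  checkSameLabels(colnames(s), colnames(a), "scores/association disease")
  stopIfNot(disease %in% colnames(s), "unknown disease label: ", disease)
  stopIfNot(topK >= 1L, "topK must be at least 1")
  cand <- rownames(s)
  if (excludeKnown) cand <- cand[a[, disease] == 0]
  ord <- cand[order(-s[cand, disease], cand)]
  top <- utils::head(ord, topK)
  data.frame(mirna = top, score = s[top, disease], rank = seq_along(top),
             row.names = NULL, stringsAsFactors = FALSE)
}
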