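test_that("global-rank AUC matches brute-force pair counting, including ties", {
  expect_equal(globalRankAuc(0.9, c(0.1, 0.5)), 1)
  expect_equal(globalRankAuc(0.3, c(0.1, 0.5)), 0.5)
  expect_equal(globalRankAuc(0.5, 0.5), 0.5)
  set.seed(41)
  for (i in 1:50) {
    nt <- sample(1:40, 1); nc <- sample(1:60, 1)
    # coarse grid forces ties
    t <- sample(seq(0, 1, 0.1), nt, replace = TRUE)
    c <- sample(seq(0, 1, 0.1), nc, replace = TRUE)
    expect_identical(globalRankAuc(t, c), bruteAuc(t, c))
  }
  expect_error(globalRankAuc(numeric(0), 1), "non-empty")
})

test_that("AUC against itself saturates at 0.5 and is rank-invariant", {
  set.seed(42)
  s <- rnorm(50)
  expect_equal(globalRankAuc(s, s), 0.5)
  t <- rnorm(20); c <- rnorm(30)
  mono <- function(x) exp(3 * x) + 1  # strictly increasing
  expect_equal(globalRankAuc(mono(t), mono(c)), globalRankAuc(t, c))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  t <- rnorm(25, 1); c <- rnorm(40)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 25), rep(0, 40)), predictor = c(t, c),
    direction = "<", quiet = TRUE)))
  expect_equal(globalRankAuc(t, c), ref, tolerance = 1e-12)
})

test_that("ROC points run from (0,0) to (1,1) and integrate to the AUC", {
  b <- makeBundle(nm = 15, nd = 10, g = 2, density = 0.15, seed = 44)
  cfg <- grmdaConfig(r = 3, p = 4, q = 3, seed = 44)
  cv <- loocv(b@assoc, b@fs, b@corpus, cfg, maxFolds = 8)
  rp <- cv@rocPoints
  expect_equal(rp[1, ], c(0, 0))
  expect_equal(rp[nrow(rp), ], c(1, 1))
  expect_true(!is.unsorted(rp[, 1]) && !is.unsorted(rp[, 2]))
  expect_true(cv@auc >= 0 && cv@auc <= 1)
})

test_that("LOOCV executes one fold per known association and is seeded", {
  a <- AssociationMatrix(matrix(c(1, 0, 0, 0, 1, 0), 3, 2),
                         paste0("m", 1:3), paste0("d", 1:2))
  fs <- SimilarityMatrix(diag(3), labels = paste0("m", 1:3), role = "FS")
  ed <- withr::local_tempfile(lines = "d1\troot")
  mem <- withr::local_tempfile(lines = c("d1\td1", "d2\troot"))
  corpus <- loadDagCorpus(ed, mem)
  cfg <- grmdaConfig(r = 1, p = 2, q = 1, seed = 5)
  cv <- loocv(a, fs, corpus, cfg)
  expect_identical(cv@nFolds, 2L)
  expect_equal(cv@aucSd, 0)
  cv2 <- loocv(a, fs, corpus, cfg)
  expect_identical(cv@auc, cv2@auc)
  expect_identical(cv@rocPoints, cv2@rocPoints)
})

test_that("an oracle scorer that sees the unmasked matrix achieves AUC 1", {
  b <- makeBundle(nm = 12, nd = 8, g = 2, density = 0.2, seed = 45)
  a <- as.matrix(b@assoc)
  oracle <- function(masked) ScoreMatrix(a)
  cv <- loocv(b@assoc, b@fs, b@corpus, grmdaConfig(seed = 45), scorer = oracle)
  expect_equal(cv@auc, 1)
})

test_that("k-fold partitions are disjoint, exhaustive and near-equal", {
  set.seed(46)
  for (n in c(10, 23, 57)) {
    idx <- sample(1000, n)
    folds <- grmda:::.partitionFolds(idx, 5)
    expect_length(folds, 5)
    expect_setequal(unlist(folds), idx)
    expect_equal(sum(lengths(folds)), n)
    expect_lte(diff(range(lengths(folds))), 1)
  }
  expect_equal(unname(lengths(grmda:::.partitionFolds(1:10, 5))), rep(2, 5))
})

test_that("repeated five-fold CV keeps one AUC per repetition, reproducibly", {
  b <- makeBundle(nm = 15, nd = 10, g = 2, density = 0.2, seed = 47)
  a <- as.matrix(b@assoc)
  # cheap deterministic scorer keeps the protocol test fast
  degree <- function(masked) {
    m <- as.matrix(masked)
    ScoreMatrix(outer(rowSums(m), colSums(m)) + 1e-9 * seq_along(m))
  }
  cfg <- grmdaConfig(seed = 99)
  cv <- kfoldCv(b@assoc, b@fs, b@corpus, cfg, k = 5, reps = 3, scorer = degree)
  expect_length(cv@perRepAucs, 3)
  expect_equal(cv@auc, mean(cv@perRepAucs))
  expect_equal(cv@aucSd, sd(cv@perRepAucs))
  expect_identical(cv@nFolds, 5L)
  cv2 <- kfoldCv(b@assoc, b@fs, b@corpus, cfg, k = 5, reps = 3, scorer = degree)
  expect_identical(cv@perRepAucs, cv2@perRepAucs)
  expect_error(kfoldCv(b@assoc, b@fs, b@corpus, cfg, k = nrow(a) * ncol(a)),
               "fewer known")
})

test_that("zeroing a disease column copies rather than mutates", {
  a <- toyAssoc()
  z <- zeroDiseaseColumn(a, "d2")
  expect_equal(unname(as.matrix(z)[, "d2"]), rep(0, 3))
  expect_equal(as.matrix(z)[, "d1"], as.matrix(a)[, "d1"])
  expect_equal(sum(as.matrix(a)), 4)  # input unchanged
  expect_error(zeroDiseaseColumn(a, "nope"), "unknown disease")
})

test_that("per-disease ranking orders by score with label tie-breaks", {
  s <- ScoreMatrix(matrix(c(0.2, 0.9, 0.9), 3, 1),
                   c("mC", "mA", "mB"), "d1")
  a <- AssociationMatrix(matrix(c(0, 0, 1), 3, 1),
                         c("mC", "mA", "mB"), "d1")
  all <- rankForDisease(s, a, "d1", excludeKnown = FALSE, topK = 3)
  expect_identical(all$mirna, c("mA", "mB", "mC"))  # tie mA/mB by label
  expect_identical(all$rank, 1:3)
  excl <- rankForDisease(s, a, "d1", excludeKnown = TRUE, topK = 10)
  expect_identical(excl$mirna, c("mA", "mC"))
  expect_identical(rankForDisease(s, a, "d1", topK = 1)$mirna, "mA")
  expect_error(rankForDisease(s, a, "dX"), "unknown disease")
})

test_that("rankings are invariant under increasing score transforms", {
  set.seed(48)
  s <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("m", 1:10), paste0("d", 1:4)))
  a <- matrix(rbinom(40, 1, 0.2), 10, 4, dimnames = dimnames(s))
  r1 <- rankForDisease(ScoreMatrix(s), AssociationMatrix(a), "d2", topK = 10)
  r2 <- rankForDisease(ScoreMatrix(pnorm(s)), AssociationMatrix(a), "d2",
                       topK = 10)
  expect_identical(r1$mirna, r2$mirna)
})

test_that("cross-validation results serialize to JSON with ROC TSV", {
  b <- makeBundle(nm = 12, nd = 8, g = 2, density = 0.2, seed = 49)
  oracle <- function(masked) ScoreMatrix(as.matrix(b@assoc))
  cv <- loocv(b@assoc, b@fs, b@corpus, grmdaConfig(seed = 49), scorer = oracle)
  out <- withr::local_tempfile(fileext = ".json")
  roc <- withr::local_tempfile(fileext = ".tsv")
  writeCvResult(cv, out, rocPath = roc)
  j <- jsonlite::read_json(out)
  expect_equal(j$auc, 1)
  expect_equal(j$n_folds, cv@nFolds)
  expect_identical(colnames(read.delim(roc)), c("FPR", "TPR"))
})
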