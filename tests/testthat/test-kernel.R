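test_that("kernel toys match hand-computed bandwidth and distances", {
  a <- toyAssoc()
  kd <- as.matrix(diseaseKernel(a))
  expect_equal(kd["d1", "d2"], exp(-1))    # mean norm 2, distance 2
  expect_equal(diag(kd), c(d1 = 1, d2 = 1))
  km <- as.matrix(mirnaKernel(a))
  expect_equal(km["m1", "m2"], exp(-1.5))  # gamma_m = 3/4, distance 2
  expect_equal(km["m3", "m3"], 1)
  expect_true(isSymmetric(km))
})

test_that("duplicate profiles score 1 and single-profile kernels are [[1]]", {
  dup <- AssociationMatrix(matrix(c(1, 0, 1, 0), 2, 2),  # equal columns
                           c("m1", "m2"), c("d1", "d2"))
  expect_equal(as.matrix(diseaseKernel(dup))["d1", "d2"], 1)
  one <- AssociationMatrix(matrix(c(1, 0), 2, 1), c("m1", "m2"), "d1")
  expect_equal(unname(as.matrix(diseaseKernel(one))), matrix(1, 1, 1))
})

test_that("an all-zero profile matrix falls back to gamma = gammaPrime with a warning", {
  z <- matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_warning(k <- gaussianKernel(z), "zero")
  expect_equal(unname(as.matrix(k)), matrix(1, 2, 2))
  # a single zero profile among informative ones models a new disease
  p <- matrix(c(0, 0, 0, 1, 0, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("new", "d1"), NULL))
  k2 <- as.matrix(gaussianKernel(p))      # mean norm 1, gamma 1, dist 2
  expect_equal(k2["new", "d1"], exp(-2))
  expect_equal(k2["new", "new"], 1)
})

test_that("kernel entries decrease strictly with profile distance", {
  set.seed(21)
  prof <- matrix(rbinom(10 * 20, 1, 0.3), 10, 20,
                 dimnames = list(paste0("p", 1:10), NULL))
  k <- as.matrix(gaussianKernel(prof))
  d2 <- as.matrix(dist(prof))^2
  off <- upper.tri(k)
  ord <- order(d2[off])
  expect_true(all(diff(k[off][ord]) <= 1e-12))
  expect_true(all(k > 0 & k <= 1))
})

test_that("kernels are equivariant under simultaneous permutation of A", {
  set.seed(22)
  a <- matrix(rbinom(8 * 6, 1, 0.3), 8, 6,
              dimnames = list(paste0("m", 1:8), paste0("d", 1:6)))
  pm <- sample(8)
  km1 <- as.matrix(mirnaKernel(AssociationMatrix(a)))
  km2 <- as.matrix(mirnaKernel(AssociationMatrix(a[pm, ])))
  expect_equal(km2, km1[pm, pm])
  pd <- sample(6)
  kd1 <- as.matrix(diseaseKernel(AssociationMatrix(a)))
  kd2 <- as.matrix(diseaseKernel(AssociationMatrix(a[, pd])))
  expect_equal(kd2, kd1[pd, pd])
})

test_that("flipping one association only rescales the kernel through the bandwidth", {
  set.seed(23)
  a1 <- matrix(rbinom(6 * 5, 1, 0.4), 6, 5,
               dimnames = list(paste0("m", 1:6), paste0("d", 1:5)))
  a1[1, 1] <- 0
  a2 <- a1
  a2[1, 1] <- 1
  k1 <- as.matrix(mirnaKernel(AssociationMatrix(a1)))
  k2 <- as.matrix(mirnaKernel(AssociationMatrix(a2)))
  g1 <- 1 / mean(rowSums(a1^2))
  g2 <- 1 / mean(rowSums(a2^2))
  # profile distances away from row 1 are unchanged: entries differ only by
  # the bandwidth exponent
  untouched <- 2:6
  expect_equal(k2[untouched, untouched], k1[untouched, untouched]^(g2 / g1))
})

test_that("integrated disease similarity averages semantic models under the mask", {
  labs <- c("a", "b")
  mk <- function(x, role) SimilarityMatrix(matrix(c(1, x, x, 1), 2, 2),
                                           labels = labs, role = role)
  ss1 <- mk(0.4, "SS1"); ss2 <- mk(0.2, "SS2"); kd <- mk(exp(-1), "KD")
  maskT <- matrix(TRUE, 2, 2, dimnames = list(labs, labs))
  sd1 <- as.matrix(integrateDiseaseSimilarity(ss1, ss2, kd, maskT))
  expect_equal(sd1["a", "b"], 0.3)
  expect_equal(diag(sd1), c(a = 1, b = 1))
  maskF <- maskT; maskF[] <- FALSE
  sd2 <- as.matrix(integrateDiseaseSimilarity(ss1, ss2, kd, maskF))
  expect_equal(sd2["a", "b"], exp(-1))
  bad <- SimilarityMatrix(matrix(c(1, .4, .4, 1), 2, 2), labels = c("b", "a"))
  expect_error(integrateDiseaseSimilarity(bad, ss2, kd, maskT), "label")
})

test_that("integrated miRNA similarity keeps FS where known, kernel elsewhere", {
  labs <- c("m1", "m2", "m3")
  fsv <- matrix(0, 3, 3, dimnames = list(labs, labs))
  fsv[1, 2] <- fsv[2, 1] <- 0.7
  diag(fsv) <- 1
  fs <- SimilarityMatrix(fsv, role = "FS")
  kmv <- matrix(exp(-1.5), 3, 3, dimnames = list(labs, labs))
  diag(kmv) <- 1
  km <- SimilarityMatrix(kmv, role = "KM")
  sm <- as.matrix(integrateMirnaSimilarity(fs, km))
  expect_equal(sm["m1", "m2"], 0.7)          # functional branch
  expect_equal(sm["m1", "m3"], exp(-1.5))    # kernel fallback
  expect_equal(diag(sm), c(m1 = 1, m2 = 1, m3 = 1))
})

test_that("integration leaves semantic/functional branch entries untouched by one flip", {
  set.seed(24)
  b <- makeBundle(nm = 15, nd = 10, g = 2, density = 0.15, seed = 24)
  cfg <- grmdaConfig()
  s1 <- integratedSimilarities(b@assoc, b@fs, b@corpus, cfg)
  a2 <- as.matrix(b@assoc)
  known <- which(a2 == 1)
  a2[known[1]] <- 0
  s2 <- integratedSimilarities(AssociationMatrix(a2), b@fs, b@corpus, cfg)
  fsMask <- as.matrix(b@fs) > 0
  expect_equal(as.matrix(s2$sm)[fsMask], as.matrix(s1$sm)[fsMask])
  semMask <- s1$semantic$mask
  expect_equal(as.matrix(s2$sd)[semMask], as.matrix(s1$sd)[semMask])
})
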