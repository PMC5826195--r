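test_that("truncated factorization reproduces the hand-worked diagonal case", {
  f <- truncatedFactorize(diag(c(2, 1)), 1)
  expect_equal(unname(f@left[, 1]), c(sqrt(2), 0))
  expect_equal(unname(f@right[, 1]), c(sqrt(2), 0))
  expect_equal(unname(tcrossprod(f@left, f@right)),
               matrix(c(2, 0, 0, 0), 2, 2))
  expect_equal(f@d, 2)
})

test_that("full-rank factorization reconstructs exactly; bad k errors", {
  set.seed(31)
  m <- matrix(rnorm(30), 6, 5)
  f <- truncatedFactorize(m, 5)
  expect_lt(norm(tcrossprod(f@left, f@right) - m, "F"), 1e-10 * norm(m, "F"))
  expect_error(truncatedFactorize(m, 6), "k must be")
  expect_error(truncatedFactorize(m, 0), "k must be")
  m[1, 1] <- NA
  expect_error(truncatedFactorize(m, 2), "finite")
})

test_that("truncation residual equals the discarded spectrum (Eckart-Young)", {
  set.seed(32)
  for (i in 1:10) {
    n <- sample(5:30, 1); m <- sample(4:25, 1)
    x <- matrix(rnorm(n * m), n, m)
    d <- svd(x)$d
    for (k in unique(c(1, sample(seq_len(min(n, m)), 3)))) {
      f <- truncatedFactorize(x, k)
      res2 <- norm(tcrossprod(f@left, f@right) - x, "F")^2
      expect_equal(res2, sum(d[-seq_len(k)]^2), tolerance = 1e-6)
    }
  }
})

test_that("singular vector signs follow the largest-magnitude rule deterministically", {
  set.seed(33)
  m <- matrix(rnorm(48), 8, 6)
  f1 <- truncatedFactorize(m, 4)
  f2 <- truncatedFactorize(m, 4)
  expect_identical(f1@left, f2@left)
  u <- f1@left %*% diag(1 / sqrt(f1@d))
  for (k in 1:4) expect_gte(u[which.max(abs(u[, k])), k], 0)
})

test_that("symmetric factorization squares back to PSD inputs", {
  f <- symmetricFactorize(diag(c(4, 1)), 2)
  expect_equal(unname(tcrossprod(f@left)), diag(c(4, 1)))
  f1 <- symmetricFactorize(diag(c(4, 1)), 1)
  expect_equal(unname(tcrossprod(f1@left)), diag(c(4, 0)))
  fi <- symmetricFactorize(diag(3), 3)
  expect_equal(unname(tcrossprod(fi@left)), diag(3))
  expect_error(symmetricFactorize(matrix(c(1, 2, 3, 4), 2, 2), 1), "symmetric")
})

test_that("PLS at full components recovers a noiseless linear map and matches OLS", {
  set.seed(34)
  n <- 40; f <- 5; t <- 7   # t >= f so full components reach rank(X)
  x <- matrix(rnorm(n * f), n, f)
  b0 <- matrix(rnorm(f * t), f, t)
  y <- x %*% b0
  fit <- plsFit(x, y, fraction = 1)
  pred <- x %*% fit$B + rep(fit$intercept, each = n)
  expect_lt(norm(pred - y, "F"), 1e-8 * norm(y, "F"))
  # independent oracle: full-component PLS equals ordinary least squares
  ynoisy <- y + matrix(rnorm(n * t, 0, 0.3), n, t)
  fit2 <- plsFit(x, ynoisy, fraction = 1)
  ols <- stats::lm.fit(cbind(1, x), ynoisy)
  predPls <- x %*% fit2$B + rep(fit2$intercept, each = n)
  predOls <- cbind(1, x) %*% ols$coefficients
  expect_lt(norm(predPls - predOls, "F"), 1e-8 * norm(predOls, "F"))
})

test_that("PLS degenerate cases: zero targets, constant features, tiny n", {
  set.seed(35)
  x <- matrix(rnorm(20), 10, 2)
  fit <- plsFit(x, matrix(0, 10, 3), fraction = 0.9)
  expect_equal(fit$B, matrix(0, 2, 3))
  expect_equal(fit$intercept, rep(0, 3))
  expect_error(plsFit(matrix(1, 10, 2), matrix(rnorm(10), 10, 1)), "constant")
  expect_error(plsFit(matrix(1, 1, 1), matrix(1, 1, 1)), "2 samples")
})

test_that("component counts follow the floored-fraction rule", {
  set.seed(36)
  x <- matrix(rnorm(30 * 6), 30, 6)
  y <- matrix(rnorm(30 * 4), 30, 4)
  fit <- plsFit(x, y, fraction = 0.9)
  expect_identical(fit$ncomp, max(1L, as.integer(floor(0.9 * min(6, 4, 29)))))
  # reference dimensions: floor(0.9 * min(220, 180, 494)) = 162
  dims <- resolveDimensions(495, 383, grmdaConfig(p = 220, q = 170, r = 180))
  expect_identical(dims$ncompMirna, 162L)
})

test_that("dimension resolution applies fractions, pass-through and clipping", {
  cfg <- grmdaConfig()
  dims <- resolveDimensions(495, 383, cfg)
  expect_identical(dims[c("r", "p", "q")], list(r = 180L, p = 223L, q = 172L))
  explicit <- resolveDimensions(495, 383, grmdaConfig(p = 220, q = 170, r = 180))
  expect_identical(explicit[c("r", "p", "q")], list(r = 180L, p = 220L, q = 170L))
  expect_warning(clipped <- resolveDimensions(10, 8, grmdaConfig(p = 99)),
                 "clipped")
  expect_identical(clipped$p, 10L)
})

test_that("the scoring pipeline equals a straight-line composition of its steps", {
  set.seed(37)
  b <- makeBundle(nm = 10, nd = 8, g = 2, density = 0.2, seed = 37)
  cfg <- grmdaConfig(r = 3, p = 4, q = 3, seed = 37)
  sims <- integratedSimilarities(b@assoc, b@fs, b@corpus, cfg)
  got <- as.matrix(grmdaScore(b@assoc, sims$sm, sims$sd, cfg))

  # reference: base svd + mixOmics pls composed inline, no package wrappers
  fixsign <- function(u, v) {
    for (k in seq_len(ncol(u))) {
      i <- which.max(abs(u[, k]))
      if (u[i, k] < 0) { u[, k] <- -u[, k]; v[, k] <- -v[, k] }
    }
    list(u = u, v = v)
  }
  trunc <- function(m, k) {
    s <- svd(m); fx <- fixsign(s$u[, 1:k, drop = FALSE], s$v[, 1:k, drop = FALSE])
    list(L = fx$u %*% diag(sqrt(s$d[1:k]), k), R = fx$v %*% diag(sqrt(s$d[1:k]), k))
  }
  refPls <- function(x, y, frac) {
    nc <- max(1, floor(frac * min(ncol(x), ncol(y), nrow(x) - 1)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    colnames(y) <- paste0("t", seq_len(ncol(y)))
    fit <- mixOmics::pls(x, y, ncomp = nc, scale = FALSE, mode = "regression")
    bh <- predict(fit, x)$B.hat
    B <- matrix(if (length(dim(bh)) == 3) bh[, , nc] else bh, ncol(x), ncol(y))
    list(B = B, b0 = colMeans(y) - as.numeric(colMeans(x) %*% B))
  }
  a <- as.matrix(b@assoc)
  fa <- trunc(a, 3)
  fr <- trunc(as.matrix(sims$sm), 4)$L
  fd <- trunc(as.matrix(sims$sd), 3)$L
  br <- refPls(fr, fa$L, 0.9)
  bd <- refPls(fd, fa$R, 0.9)
  want <- (fr %*% br$B + rep(br$b0, each = nrow(fr))) %*%
    t(fd %*% bd$B + rep(bd$b0, each = nrow(fd)))
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("scoring is deterministic and permutation-equivariant", {
  b <- makeBundle(nm = 12, nd = 9, g = 2, density = 0.2, seed = 38)
  cfg <- grmdaConfig(r = 3, p = 4, q = 3)
  sims <- integratedSimilarities(b@assoc, b@fs, b@corpus, cfg)
  c1 <- as.matrix(grmdaScore(b@assoc, sims$sm, sims$sd, cfg))
  c2 <- as.matrix(grmdaScore(b@assoc, sims$sm, sims$sd, cfg))
  expect_identical(c1, c2)
  expect_identical(dimnames(c1), dimnames(as.matrix(b@assoc)))

  set.seed(39)
  pm <- sample(nrow(c1))
  aP <- AssociationMatrix(as.matrix(b@assoc)[pm, ])
  smP <- SimilarityMatrix(as.matrix(sims$sm)[pm, pm], role = "Sm")
  cP <- as.matrix(grmdaScore(aP, smP, sims$sd, cfg))
  expect_equal(cP, c1[pm, ], tolerance = 1e-8)
})

test_that("known associations outscore non-associations on a planted structure", {
  # noiseless planted structure: A thresholded from a low-rank product,
  # similarities = cosine similarity of the true factors
  set.seed(40)
  nm <- 30; nd <- 20; g <- 3
  X <- matrix(rgamma(nm * g, 2), nm); Y <- matrix(rgamma(nd * g, 2), nd)
  P <- X %*% t(Y)
  a <- (P > quantile(P, 0.8)) * 1
  dimnames(a) <- list(paste0("m", 1:nm), paste0("d", 1:nd))
  cos <- function(Z) { n <- sqrt(rowSums(Z^2)); s <- tcrossprod(Z / n); diag(s) <- 1; pmin(pmax(s, 0), 1) }
  sm <- SimilarityMatrix(cos(X), labels = rownames(a), role = "Sm")
  sd <- SimilarityMatrix(cos(Y), labels = colnames(a), role = "Sd")
  cfg <- grmdaConfig(r = 5, p = 6, q = 5)
  s <- as.matrix(grmdaScore(AssociationMatrix(a), sm, sd, cfg))
  expect_gt(mean(s[a == 1]), mean(s[a == 0]))
})
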