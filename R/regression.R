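# Fix singular-vector signs deterministically: each column of U gets a
# non-negative entry of largest magnitude; V columns flip in step.
.fixSigns <- function(u, v) {
  for (k in seq_len(ncol(u))) {
    i <- which.max(abs(u[, k]))
    if (u[i, k] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  list(u = u, v = v)
}

#' Truncated SVD factorization of a matrix
#'
#' Computes the singular value decomposition, keeps the top-k triplets and
#' splits the singular values symmetrically between the factors:
#' \eqn{L = U_k \Sigma_k^{1/2}}, \eqn{R = V_k \Sigma_k^{1/2}}, so that
#' \eqn{L R^T = U_k \Sigma_k V_k^T} is the best rank-k approximation
#' (Eckart-Young: the squared Frobenius residual equals the sum of the
#' discarded squared singular values). Signs are fixed so each column of U
#' has a non-negative entry of largest magnitude, making the result
#' deterministic across platforms.
#'
#' @param m numeric matrix (all entries finite).
#' @param k number of retained components, 1 <= k <= min(dim(m)).
#' @param role role tag for the result (default "association").
#' @return a [Factorization].
#' @export
#' @examples
#' f <- truncatedFactorize(diag(c(2, 1)), 1)
#' tcrossprod(f@left, f@right)  # rank-1 reconstruction [[2,0],[0,0]]
truncatedFactorize <- function(m, k, role = "association") {
  m <- as.matrix(m)
  stopIfNot(all(is.finite(m)), "matrix must be finite")
  stopIfNot(length(k) == 1L && k == round(k) && k >= 1 && k <= min(dim(m)),
            "k must be an integer in [1, min(dim(m))] (got ", k, ")")
  s <- svd(m, nu = k, nv = k)
  fixed <- .fixSigns(s$u, s$v)
  sq <- sqrt(s$d[seq_len(k)])
  new("Factorization",
      left = fixed$u * rep(sq, each = nrow(m)),
      right = fixed$v * rep(sq, each = ncol(m)),
      d = s$d[seq_len(k)], role = role)
}

#' Truncated factorization of a symmetric similarity matrix
#'
#' As [truncatedFactorize()] but tagged for a similarity graph; the left
#' factor \eqn{F = U_k \Sigma_k^{1/2}} is the latent feature matrix. When
#' the input is positive semidefinite, \eqn{F F^T} equals the truncated
#' reconstruction (U and V coincide); components with negative eigenvalues
#' contribute a known residual instead.
#'
#' @param s a [SimilarityMatrix] or symmetric numeric matrix.
#' @param k number of retained components.
#' @param role role tag ("mirna_sim" or "disease_sim").
#' @return a [Factorization]; use \code{@left} as the feature matrix.
#' @export
symmetricFactorize <- function(s, k, role = "mirna_sim") {
  v <- if (is(s, "SimilarityMatrix")) as.matrix(s) else as.matrix(s)
  stopIfNot(nrow(v) == ncol(v) && max(abs(v - t(v))) <= 1e-9,
            "input must be symmetric")
  truncatedFactorize(v, k, role = role)
}

#' Multi-response partial least squares fit
#'
#' Fits a PLS2 regression of the responses on the features with column
#' centering only (no unit-variance scaling: the latent factors carry
#' singular-value weighting that scaling would destroy). The number of
#' components is \code{max(1, floor(fraction * min(f, t, n - 1)))} in
#' \code{"count"} mode, or the smallest count whose cumulative explained
#' feature variance reaches \code{fraction} in \code{"variance"} mode. The
#' fitting engine is the NIPALS implementation in \pkg{mixOmics}.
#'
#' @param x n x f feature matrix.
#' @param y n x t response matrix (a vector is treated as one column).
#' @param fraction fraction of components to keep, in (0, 1].
#' @param mode \code{"count"} (default) or \code{"variance"}.
#' @return list with \code{B} (f x t coefficient matrix), \code{intercept}
#'   (length-t offset) and \code{ncomp}, such that predictions are
#'   \code{x \%*\% B + intercept} (recycled by row).
#' @export
plsFit <- function(x, y, fraction = 0.9, mode = c("count", "variance")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  stopIfNot(nrow(y) == n, "feature and target row counts differ")
  stopIfNot(n >= 2L, "need at least 2 samples")
  stopIfNot(all(is.finite(x)) && all(is.finite(y)), "inputs must be finite")
  stopIfNot(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  f <- ncol(x); t <- ncol(y)
  if (all(apply(x, 2L, stats::var) < .Machine$double.eps))
    stop("all feature columns are constant; PLS is undefined", call. = FALSE)
  ybar <- colMeans(y)
  # responses constant after centering: the least-squares fit is the mean
  if (all(apply(y, 2L, stats::var) < .Machine$double.eps^0.5 * max(1, max(abs(ybar)))^2)) {
    return(list(B = matrix(0, f, t), intercept = ybar, ncomp = 1L))
  }
  ncompMax <- min(f, t, n - 1L)
  xn <- x; yn <- y
  colnames(xn) <- paste0("f", seq_len(f))
  colnames(yn) <- paste0("t", seq_len(t))
  # the engine warns about mean centering below 5 samples; centering is
  # exactly what we ask of it, so the warning is noise on tiny inputs
  quietPls <- function(...) withCallingHandlers(
    mixOmics::pls(...),
    warning = function(w) {
      if (grepl("less than 5 samples", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (mode == "count") {
    ncomp <- max(1L, as.integer(floor(fraction * ncompMax)))
    fit <- quietPls(xn, yn, ncomp = ncomp, scale = FALSE, mode = "regression")
  } else {
    fit <- quietPls(xn, yn, ncomp = ncompMax, scale = FALSE,
                    mode = "regression")
    cum <- cumsum(fit$prop_expl_var$X)
    ncomp <- which(cum >= fraction)[1]
    if (is.na(ncomp)) ncomp <- ncompMax
  }
  pr <- stats::predict(fit, xn)
  B <- if (length(dim(pr$B.hat)) == 3L) pr$B.hat[, , ncomp] else pr$B.hat
  B <- matrix(B, f, t)
  intercept <- as.numeric(ybar - colMeans(x) %*% B)
  list(B = B, intercept = intercept, ncomp = as.integer(ncomp))
}

#' Score all miRNA-disease pairs by latent graph regression
#'
#' The full scoring pipeline. The association matrix A is factorized by
#' truncated SVD into latent association factors (Ar over miRNAs, Ad over
#' diseases, rank r); the integrated miRNA and disease similarity matrices
#' are factorized into latent feature matrices Fr (rank p) and Fd (rank q).
#' Two PLS regressions link the spaces — Ar on Fr and Ad on Fd — and the
#' confidence score matrix is the bilinear product of the two regression
#' predictions, \eqn{C = \hat{A}_r \hat{A}_d^T} (with
#' \code{intercept = FALSE} this is the bare
#' \eqn{C = F_r B_r B_d^T F_d^T}). Deterministic for fixed inputs and
#' configuration.
#'
#' @param assoc an [AssociationMatrix].
#' @param sm integrated miRNA [SimilarityMatrix] (role Sm), same miRNA axis.
#' @param sd integrated disease [SimilarityMatrix] (role Sd), same disease
#'   axis.
#' @param config a [GrmdaConfig]; r, p, q are resolved against the data by
#'   [resolveDimensions()].
#' @return a [ScoreMatrix] with the association matrix's labels.
#' @export
grmdaScore <- function(assoc, sm, sd, config = grmdaConfig()) {
  a <- as.matrix(assoc)
  checkSameLabels(rownames(a), simLabels(sm), "association/Sm")
  checkSameLabels(colnames(a), simLabels(sd), "association/Sd")
  dims <- resolveDimensions(nrow(a), ncol(a), config)
  fa <- truncatedFactorize(a, dims$r, role = "association")
  fr <- symmetricFactorize(sm, dims$p, role = "mirna_sim")@left
  fd <- symmetricFactorize(sd, dims$q, role = "disease_sim")@left
  # a degenerate latent feature matrix (all columns constant, possible on
  # 2-disease or duplicate-similarity inputs) carries no regression signal;
  # the limiting fit is the response mean
  meanFit <- function(x, y) list(B = matrix(0, ncol(x), ncol(y)),
                                 intercept = colMeans(y), ncomp = 1L)
  fitOrMean <- function(x, y) {
    if (all(apply(x, 2L, stats::var) < .Machine$double.eps)) meanFit(x, y)
    else plsFit(x, y, fraction = config@plsFraction, mode = config@plsMode)
  }
  br <- fitOrMean(fr, fa@left)
  bd <- fitOrMean(fd, fa@right)
  predR <- fr %*% br$B
  predD <- fd %*% bd$B
  if (config@intercept) {
    predR <- predR + rep(br$intercept, each = nrow(predR))
    predD <- predD + rep(bd$intercept, each = nrow(predD))
  }
  ScoreMatrix(tcrossprod(predR, predD),
              mirnaIds = rownames(a), diseaseIds = colnames(a))
}
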