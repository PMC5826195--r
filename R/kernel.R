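#' Gaussian interaction-profile kernel
#'
#' Similarity between binary interaction profiles: entry (i, j) is
#' \eqn{\exp(-\gamma \|row_i - row_j\|^2)} with the bandwidth
#' \eqn{\gamma = \gamma' / \overline{\|row\|^2}}, i.e. the scaler
#' gamma-prime normalized by the mean squared profile norm (the average
#' number of known associations per profile). If every profile is all-zero
#' the normalizer vanishes; the kernel then falls back to
#' \eqn{\gamma = \gamma'} with a warning (all profiles identical, kernel
#' all ones), which keeps new-disease / new-miRNA workflows total.
#'
#' @param profiles n x k binary matrix, one interaction profile per row;
#'   rownames become the result labels.
#' @param gammaPrime bandwidth scaler, > 0 (default 1).
#' @param role role tag for the result.
#' @return a [SimilarityMatrix] with unit diagonal and entries in (0, 1].
#' @export
#' @examples
#' p <- matrix(c(1, 0, 1, 0, 1, 1), 2, 3, byrow = TRUE,
#'             dimnames = list(c("d1", "d2"), NULL))
#' as.matrix(gaussianKernel(p))  # off-diagonal exp(-1)
gaussianKernel <- function(profiles, gammaPrime = 1, role = "generic") {
  profiles <- as.matrix(profiles)
  stopIfNot(nrow(profiles) >= 1L, "need at least one profile")
  stopIfNot(all(profiles %in% c(0, 1)), "profiles must be binary 0/1")
  stopIfNot(length(gammaPrime) == 1L && is.finite(gammaPrime) && gammaPrime > 0,
            "gammaPrime must be a single positive number")
  norms <- rowSums(profiles^2)
  meanNorm <- mean(norms)
  if (meanNorm == 0) {
    warning("all interaction profiles are zero; using gamma = gammaPrime",
            call. = FALSE)
    gamma <- gammaPrime
  } else {
    gamma <- gammaPrime / meanNorm
  }
  d2 <- outer(norms, norms, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # guard rounding
  k <- exp(-gamma * d2)
  diag(k) <- 1
  labels <- rownames(profiles)
  if (is.null(labels)) labels <- paste0("p", seq_len(nrow(profiles)))
  SimilarityMatrix(k, labels = labels, role = role)
}

#' Gaussian kernel over disease interaction profiles
#'
#' Disease i's interaction profile is column i of the association matrix;
#' the kernel bandwidth is gamma-prime normalized by the average number of
#' known associations per disease.
#'
#' @param assoc an [AssociationMatrix].
#' @param gammaPrimeD bandwidth scaler (default 1).
#' @return a [SimilarityMatrix] with role KD over the disease axis.
#' @export
diseaseKernel <- function(assoc, gammaPrimeD = 1) {
  gaussianKernel(t(as.matrix(assoc)), gammaPrimeD, role = "KD")
}

#' Gaussian kernel over miRNA interaction profiles
#'
#' miRNA i's interaction profile is row i of the association matrix.
#'
#' @param assoc an [AssociationMatrix].
#' @param gammaPrimeM bandwidth scaler (default 1).
#' @return a [SimilarityMatrix] with role KM over the miRNA axis.
#' @export
mirnaKernel <- function(assoc, gammaPrimeM = 1) {
  gaussianKernel(as.matrix(assoc), gammaPrimeM, role = "KM")
}

#' Integrated disease similarity
#'
#' Where a disease pair has semantic similarity (mask TRUE) the integrated
#' similarity is the average of the two semantic models, treating them as
#' equally informative; elsewhere the Gaussian interaction-profile kernel
#' supplies the value. The diagonal is 1.
#'
#' @param ss1,ss2 semantic [SimilarityMatrix] objects (roles SS1, SS2).
#' @param kd kernel [SimilarityMatrix] (role KD).
#' @param mask labelled logical matrix from [buildSemanticMatrices()].
#' @return a [SimilarityMatrix] with role Sd.
#' @export
integrateDiseaseSimilarity <- function(ss1, ss2, kd, mask) {
  checkSameLabels(simLabels(ss1), simLabels(ss2), "SS1/SS2")
  checkSameLabels(simLabels(ss1), simLabels(kd), "SS1/KD")
  checkSameLabels(simLabels(ss1), rownames(mask), "SS1/mask")
  v1 <- as.matrix(ss1); v2 <- as.matrix(ss2); vk <- as.matrix(kd)
  sd <- ifelse(mask, (v1 + v2) / 2, vk)
  diag(sd) <- 1
  SimilarityMatrix(sd, role = "Sd")
}

#' Integrated miRNA similarity
#'
#' Where a miRNA pair has functional similarity (by default: FS > 0 off the
#' diagonal) the integrated similarity is the functional similarity score;
#' elsewhere the Gaussian interaction-profile kernel fills in. The diagonal
#' is 1.
#'
#' @param fs functional [SimilarityMatrix] (role FS).
#' @param km kernel [SimilarityMatrix] (role KM).
#' @param mask optional labelled logical matrix overriding the default
#'   FS > 0 rule.
#' @return a [SimilarityMatrix] with role Sm.
#' @export
integrateMirnaSimilarity <- function(fs, km, mask = NULL) {
  checkSameLabels(simLabels(fs), simLabels(km), "FS/KM")
  vf <- as.matrix(fs); vk <- as.matrix(km)
  if (is.null(mask)) {
    mask <- vf > 0
  } else {
    checkSameLabels(simLabels(fs), rownames(mask), "FS/mask")
  }
  sm <- ifelse(mask, vf, vk)
  diag(sm) <- 1
  SimilarityMatrix(sm, role = "Sm")
}

#' Build both integrated similarity matrices from raw inputs
#'
#' Convenience wrapper running the full similarity stage: semantic
#' similarity matrices and mask from the DAG corpus, Gaussian kernels from
#' the association matrix, then the two integrations.
#'
#' @param assoc an [AssociationMatrix].
#' @param fs functional [SimilarityMatrix] over the same miRNA axis.
#' @param corpus a [DagCorpus] (may cover a subset of the diseases).
#' @param config a [GrmdaConfig] (delta and the gamma scalers are used).
#' @return list with elements \code{sm}, \code{sd} (integrated
#'   [SimilarityMatrix] objects) and \code{semantic} (the
#'   [buildSemanticMatrices()] output).
#' @export
integratedSimilarities <- function(assoc, fs, corpus, config = grmdaConfig()) {
  checkSameLabels(mirnaNames(assoc), simLabels(fs), "association/FS")
  sem <- buildSemanticMatrices(corpus, config@delta, diseaseNames(assoc))
  km <- mirnaKernel(assoc, config@gammaM)
  kd <- diseaseKernel(assoc, config@gammaD)
  list(sm = integrateMirnaSimilarity(fs, km),
       sd = integrateDiseaseSimilarity(sem$ss1, sem$ss2, kd, sem$mask),
       semantic = sem)
}
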