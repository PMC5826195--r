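#' Accessors for axis labels
#'
#' \code{mirnaNames} and \code{diseaseNames} return the ordered miRNA and
#' disease identifiers of an [AssociationMatrix] or [ScoreMatrix];
#' \code{simLabels} and \code{simRole} return the axis labels and role tag of
#' a [SimilarityMatrix].
#'
#' @param x the object.
#' @return a character vector of labels (or a single role string).
#' @name accessors
#' @aliases mirnaNames diseaseNames simLabels simRole
#' @examples
#' a <- AssociationMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("d1", "d2"))))
#' mirnaNames(a)
NULL

#' @rdname accessors
#' @export
setGeneric("mirnaNames", function(x) standardGeneric("mirnaNames"))
#' @rdname accessors
#' @export
setGeneric("diseaseNames", function(x) standardGeneric("diseaseNames"))
#' @rdname accessors
#' @export
setGeneric("simLabels", function(x) standardGeneric("simLabels"))
#' @rdname accessors
#' @export
setGeneric("simRole", function(x) standardGeneric("simRole"))

#' @rdname accessors
setMethod("mirnaNames", "AssociationMatrix", function(x) rownames(x@assoc))
#' @rdname accessors
setMethod("diseaseNames", "AssociationMatrix", function(x) colnames(x@assoc))
#' @rdname accessors
setMethod("mirnaNames", "ScoreMatrix", function(x) rownames(x@scores))
#' @rdname accessors
setMethod("diseaseNames", "ScoreMatrix", function(x) colnames(x@scores))
#' @rdname accessors
setMethod("simLabels", "SimilarityMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("simRole", "SimilarityMatrix", function(x) x@role)
#' @rdname accessors
setMethod("mirnaNames", "SyntheticBundle", function(x) mirnaNames(x@assoc))
#' @rdname accessors
setMethod("diseaseNames", "SyntheticBundle", function(x) diseaseNames(x@assoc))

#' Extract the underlying numeric matrix
#'
#' @param x an [AssociationMatrix], [SimilarityMatrix] or [ScoreMatrix].
#' @param ... ignored.
#' @return the plain numeric matrix with dimnames.
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) x@assoc)
#' @rdname as.matrix-AssociationMatrix-method
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)
#' @rdname as.matrix-AssociationMatrix-method
#' @export
setMethod("as.matrix", "ScoreMatrix", function(x, ...) x@scores)

#' Diseases covered by a DAG corpus
#'
#' @param x a [DagCorpus].
#' @return character vector of covered disease labels.
#' @export
setGeneric("corpusDiseases", function(x) standardGeneric("corpusDiseases"))
#' @rdname corpusDiseases
setMethod("corpusDiseases", "DagCorpus", function(x) x@diseases)

#' Retrieve one disease's DAG descriptor
#'
#' @param x a [DagCorpus].
#' @param disease a covered disease label.
#' @return list with elements \code{node} (the disease's own node),
#'   \code{nodes} (the node set T(D)) and \code{edges} (2-column
#'   parent/child matrix E(D)).
#' @export
setGeneric("diseaseDag", function(x, disease) standardGeneric("diseaseDag"))
#' @rdname diseaseDag
setMethod("diseaseDag", "DagCorpus", function(x, disease) {
  if (!(disease %in% x@diseases))
    stop("disease '", disease, "' is not covered by the corpus", call. = FALSE)
  x@dags[[disease]]
})

setMethod("show", "AssociationMatrix", function(object) {
  a <- object@assoc
  cat(sprintf("AssociationMatrix: %d miRNAs x %d diseases, %d known associations (density %.4f)\n",
              nrow(a), ncol(a), sum(a), mean(a)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  cat(sprintf("SimilarityMatrix [%s]: %d x %d, off-diagonal range [%.4f, %.4f]\n",
              object@role, nrow(v), ncol(v),
              if (nrow(v) > 1) min(v[row(v) != col(v)]) else NA_real_,
              if (nrow(v) > 1) max(v[row(v) != col(v)]) else NA_real_))
})

setMethod("show", "DagCorpus", function(object) {
  sizes <- vapply(object@dags, function(d) length(d$nodes), integer(1))
  cat(sprintf("DagCorpus: %d diseases over %d terms; |T(D)| in [%d, %d]\n",
              length(object@diseases), length(object@terms), min(sizes), max(sizes)))
})

setMethod("show", "GrmdaConfig", function(object) {
  cat("GrmdaConfig:\n")
  cat(sprintf("  delta = %g, gammaD = %g, gammaM = %g\n",
              object@delta, object@gammaD, object@gammaM))
  cat(sprintf("  r = %g, p = %g, q = %g (values < 1 are fractions of the axis)\n",
              object@r, object@p, object@q))
  cat(sprintf("  plsFraction = %g (%s mode), intercept = %s, recomputeKernels = %s, seed = %s\n",
              object@plsFraction, object@plsMode, object@intercept,
              object@recomputeKernels,
              if (is.na(object@seed)) "NA" else object@seed))
})

setMethod("show", "Factorization", function(object) {
  cat(sprintf("Factorization [%s]: %d x %d and %d x %d factors, k = %d, sigma1 = %.4f\n",
              object@role, nrow(object@left), ncol(object@left),
              nrow(object@right), ncol(object@right),
              length(object@d), object@d[1]))
})

setMethod("show", "ScoreMatrix", function(object) {
  s <- object@scores
  cat(sprintf("ScoreMatrix: %d miRNAs x %d diseases, score range [%.4f, %.4f]\n",
              nrow(s), ncol(s), min(s), max(s)))
})

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult: AUC = %.4f +/- %.4f over %d repetition(s), %d fold(s), seed = %s\n",
              object@auc, object@aucSd, length(object@perRepAucs), object@nFolds,
              if (is.na(object@seed)) "NA" else object@seed))
})

setMethod("show", "SyntheticBundle", function(object) {
  cat("SyntheticBundle:\n  ")
  show(object@assoc)
  cat("  ")
  show(object@fs)
  cat("  ")
  show(object@corpus)
})

#' Construct an AssociationMatrix
#'
#' @param values numeric 0/1 matrix. If \code{mirnaIds}/\code{diseaseIds}
#'   are given they replace the dimnames.
#' @param mirnaIds,diseaseIds optional character labels.
#' @return a validated [AssociationMatrix].
#' @export
#' @examples
#' AssociationMatrix(matrix(c(1, 0, 0, 1), 2, 2), c("m1", "m2"), c("d1", "d2"))
AssociationMatrix <- function(values, mirnaIds = NULL, diseaseIds = NULL) {
  values <- as.matrix(values)
  if (!is.null(mirnaIds)) rownames(values) <- mirnaIds
  if (!is.null(diseaseIds)) colnames(values) <- diseaseIds
  new("AssociationMatrix", assoc = values)
}

#' Construct a SimilarityMatrix
#'
#' Symmetrizes tiny numerical asymmetry (below 1e-9) and validates range,
#' labels and the role's diagonal requirement.
#'
#' @param values square numeric matrix.
#' @param labels optional axis labels (defaults to the dimnames).
#' @param role one of FS, SS1, SS2, KD, KM, Sd, Sm, generic.
#' @return a validated [SimilarityMatrix].
#' @export
SimilarityMatrix <- function(values, labels = NULL, role = "generic") {
  values <- as.matrix(values)
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  if (nrow(values) == ncol(values) && all(is.finite(values))) {
    asym <- max(abs(values - t(values)))
    if (asym > 0 && asym <= 1e-9) values <- (values + t(values)) / 2
  }
  new("SimilarityMatrix", values = values, role = role)
}

#' Construct a ScoreMatrix
#'
#' @param values finite numeric matrix with miRNA rownames and disease
#'   colnames (or supply them via \code{mirnaIds}/\code{diseaseIds}).
#' @param mirnaIds,diseaseIds optional character labels.
#' @return a validated [ScoreMatrix].
#' @export
ScoreMatrix <- function(values, mirnaIds = NULL, diseaseIds = NULL) {
  values <- as.matrix(values)
  if (!is.null(mirnaIds)) rownames(values) <- mirnaIds
  if (!is.null(diseaseIds)) colnames(values) <- diseaseIds
  new("ScoreMatrix", scores = values)
}
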