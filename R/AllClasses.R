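#' @import methods
NULL

.checkLabels <- function(labels, what) {
  if (length(labels) < 1L) return(sprintf("%s must have at least one label", what))
  if (anyNA(labels) || any(!nzchar(labels)))
    return(sprintf("%s labels must be non-empty strings", what))
  if (anyDuplicated(labels))
    return(sprintf("%s labels must be unique", what))
  NULL
}

#' Binary miRNA-disease association matrix
#'
#' Wraps the bipartite adjacency matrix \eqn{A} (\code{nm} miRNAs by
#' \code{nd} diseases). Row \code{i} is the interaction profile
#' \eqn{IP(m(i))} of miRNA \code{i}; column \code{j} is the interaction
#' profile \eqn{IP(d(j))} of disease \code{j}. Entries are exactly 0 or 1
#' (1 = experimentally supported association). Row and column names carry
#' the miRNA and disease identifiers and fix the axis orderings used by
#' every downstream matrix.
#'
#' @slot assoc numeric matrix of 0/1 values with unique dimnames.
#' @seealso [loadAssociations()], [mirnaKernel()], [grmdaScore()]
#' @export
setClass("AssociationMatrix", representation(assoc = "matrix"))

setValidity("AssociationMatrix", function(object) {
  a <- object@assoc
  if (!is.numeric(a)) return("association values must be numeric")
  if (nrow(a) < 1L || ncol(a) < 1L) return("need at least one miRNA and one disease")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("association matrix must carry miRNA rownames and disease colnames")
  msg <- .checkLabels(rownames(a), "miRNA")
  if (!is.null(msg)) return(msg)
  msg <- .checkLabels(colnames(a), "disease")
  if (!is.null(msg)) return(msg)
  if (anyNA(a) || !all(a %in% c(0, 1)))
    return("every association entry must be exactly 0 or 1")
  TRUE
})

.SIM_ROLES <- c("FS", "SS1", "SS2", "KD", "KM", "Sd", "Sm", "generic")
.UNIT_DIAG_ROLES <- c("KD", "KM", "Sd", "Sm")

#' Labelled symmetric similarity matrix
#'
#' A square symmetric matrix over one labelled axis (miRNAs or diseases),
#' tagged with the role it plays in the pipeline: \code{FS} (miRNA
#' functional similarity), \code{SS1}/\code{SS2} (DAG semantic similarity,
#' models 1 and 2), \code{KD}/\code{KM} (Gaussian interaction-profile
#' kernels), \code{Sd}/\code{Sm} (integrated similarities) or
#' \code{generic}. All entries lie in [0, 1] and the matrix is symmetric to
#' within 1e-9; kernel and integrated roles additionally have a unit
#' diagonal. Semantic roles may have diagonal 0 for diseases lacking a DAG.
#'
#' @slot values numeric matrix with identical row/column labels.
#' @slot role character scalar, one of the roles above.
#' @seealso [loadSimilarity()], [gaussianKernel()], [buildSemanticMatrices()]
#' @export
setClass("SimilarityMatrix",
         representation(values = "matrix", role = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (length(object@role) != 1L || !(object@role %in% .SIM_ROLES))
    return(sprintf("role must be one of: %s", paste(.SIM_ROLES, collapse = ", ")))
  if (!is.numeric(v)) return("similarity values must be numeric")
  if (nrow(v) != ncol(v)) return("similarity matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("similarity matrix must carry labels as dimnames")
  msg <- .checkLabels(rownames(v), "similarity")
  if (!is.null(msg)) return(msg)
  if (!identical(rownames(v), colnames(v)))
    return("row and column labels must match in the same order")
  if (!all(is.finite(v))) return("similarity entries must all be finite")
  if (max(abs(v - t(v))) > 1e-9)
    return("similarity matrix must be symmetric to within 1e-9")
  if (min(v) < 0 || max(v) > 1)
    return("similarity entries must lie in [0, 1]")
  if (object@role %in% .UNIT_DIAG_ROLES && any(abs(diag(v) - 1) > 1e-9))
    return(sprintf("role %s requires a unit diagonal", object@role))
  TRUE
})

#' Corpus of per-disease ontology DAGs
#'
#' Holds, for each covered disease, the descriptor \eqn{DAG(D) = (D, T(D),
#' E(D))}: the node identified with the disease itself, the node set
#' \eqn{T(D)} (the disease's node plus all its ancestors), and the induced
#' parent-to-child edge set \eqn{E(D)}. \code{terms} is the shared node
#' vocabulary; \code{membership} maps each covered disease label to its own
#' node. Diseases absent from the corpus simply have no DAG (their semantic
#' similarity is 0 and the Gaussian kernel is used instead).
#'
#' @slot diseases character vector of covered disease labels.
#' @slot membership named character: disease label -> its own DAG node.
#' @slot dags named list; each element is \code{list(node, nodes, edges)}
#'   where \code{edges} is a 2-column character matrix (parent, child).
#' @slot terms character vector of all DAG node identifiers.
#' @seealso [loadDagCorpus()], [randomDagCorpus()], [buildSemanticMatrices()]
#' @export
setClass("DagCorpus",
         representation(diseases = "character", membership = "character",
                        dags = "list", terms = "character"))

setValidity("DagCorpus", function(object) {
  if (length(object@diseases) < 1L) return("corpus must cover at least one disease")
  msg <- .checkLabels(object@diseases, "disease")
  if (!is.null(msg)) return(msg)
  if (!identical(sort(names(object@dags)), sort(object@diseases)))
    return("dags must be named by exactly the covered diseases")
  if (!identical(sort(names(object@membership)), sort(object@diseases)))
    return("membership must be named by exactly the covered diseases")
  for (d in object@diseases) {
    dag <- object@dags[[d]]
    if (!all(c("node", "nodes", "edges") %in% names(dag)))
      return(sprintf("dag for %s must have node/nodes/edges", d))
    if (!(dag$node %in% dag$nodes))
      return(sprintf("T(%s) must contain the disease's own node", d))
    if (nrow(dag$edges) > 0L && !all(dag$edges %in% dag$nodes))
      return(sprintf("every edge endpoint of %s must be in T(%s)", d, d))
    if (!all(dag$nodes %in% object@terms))
      return(sprintf("T(%s) must be drawn from the term vocabulary", d))
    if (nrow(dag$edges) > 0L) {
      g <- igraph::graph_from_edgelist(dag$edges, directed = TRUE)
      if (!igraph::is_dag(g)) return(sprintf("edge set of %s contains a cycle", d))
    }
  }
  TRUE
})

#' Pipeline configuration
#'
#' Tunable parameters for the scoring pipeline. \code{r}, \code{p} and
#' \code{q} are the retained-component counts for the association, miRNA
#' similarity and disease similarity spaces; a value below 1 is interpreted
#' as a fraction of the relevant dimension (resolved by
#' [resolveDimensions()]), a value of 1 or more as an explicit count.
#'
#' @slot delta semantic contribution factor, in (0, 1); default 0.5.
#' @slot gammaD,gammaM kernel bandwidth scalers (gamma-prime), both > 0;
#'   default 1.
#' @slot r,p,q retained components (count, or fraction of dimension);
#'   defaults 0.47, 0.45, 0.45.
#' @slot plsFraction fraction of PLS components to keep, in (0, 1];
#'   default 0.9.
#' @slot plsMode \code{"count"} (fraction of the maximum usable component
#'   count, the default) or \code{"variance"} (smallest count explaining
#'   that fraction of feature variance).
#' @slot intercept logical; propagate PLS centering intercepts into the
#'   score matrix (default TRUE). FALSE reproduces the bare bilinear score.
#' @slot recomputeKernels logical; rebuild the Gaussian kernels from the
#'   masked association matrix inside every cross-validation fold (default
#'   TRUE; FALSE reuses kernels from the full matrix and therefore leaks
#'   held-out associations into the similarity graphs).
#' @slot seed integer seed for all stochastic steps (NA = leave RNG alone).
#' @seealso [grmdaConfig()], [resolveDimensions()]
#' @export
setClass("GrmdaConfig",
         representation(delta = "numeric", gammaD = "numeric", gammaM = "numeric",
                        r = "numeric", p = "numeric", q = "numeric",
                        plsFraction = "numeric", plsMode = "character",
                        intercept = "logical", recomputeKernels = "logical",
                        seed = "integer"))

setValidity("GrmdaConfig", function(object) {
  scalar <- function(x) length(x) == 1L && is.finite(x)
  if (!scalar(object@delta) || object@delta <= 0 || object@delta >= 1)
    return("delta must lie strictly in (0, 1)")
  if (!scalar(object@gammaD) || object@gammaD <= 0) return("gammaD must be > 0")
  if (!scalar(object@gammaM) || object@gammaM <= 0) return("gammaM must be > 0")
  for (nm in c("r", "p", "q")) {
    v <- slot(object, nm)
    if (!scalar(v) || v <= 0) return(sprintf("%s must be positive", nm))
    if (v >= 1 && v != round(v))
      return(sprintf("%s must be a whole number when >= 1 (fractions must be < 1)", nm))
  }
  if (!scalar(object@plsFraction) || object@plsFraction <= 0 || object@plsFraction > 1)
    return("plsFraction must lie in (0, 1]")
  if (!(object@plsMode %in% c("count", "variance")))
    return("plsMode must be 'count' or 'variance'")
  if (length(object@intercept) != 1L || is.na(object@intercept))
    return("intercept must be TRUE or FALSE")
  if (length(object@recomputeKernels) != 1L || is.na(object@recomputeKernels))
    return("recomputeKernels must be TRUE or FALSE")
  if (length(object@seed) != 1L) return("seed must be a single integer or NA")
  TRUE
})

#' Truncated low-rank factorization
#'
#' The rank-k factor pair of a source graph: \code{left} and \code{right}
#' hold \eqn{L = U_k \Sigma_k^{1/2}} and \eqn{R = V_k \Sigma_k^{1/2}}, so
#' \eqn{L R^T} is the rank-k truncated SVD reconstruction. For a symmetric
#' positive semidefinite source the two factors coincide. Singular values
#' are stored in non-increasing order.
#'
#' @slot left,right numeric factor matrices (n_left x k, n_right x k).
#' @slot d numeric vector of the k retained singular values.
#' @slot role source graph: "association", "mirna_sim" or "disease_sim".
#' @seealso [truncatedFactorize()], [symmetricFactorize()]
#' @export
setClass("Factorization",
         representation(left = "matrix", right = "matrix", d = "numeric",
                        role = "character"))

setValidity("Factorization", function(object) {
  k <- length(object@d)
  if (k < 1L) return("at least one singular value must be retained")
  if (any(object@d < 0)) return("singular values must be non-negative")
  if (is.unsorted(rev(object@d))) return("singular values must be non-increasing")
  if (ncol(object@left) != k || ncol(object@right) != k)
    return("factor column counts must equal the number of singular values")
  if (!all(is.finite(object@left)) || !all(is.finite(object@right)))
    return("factors must be finite")
  if (!(object@role %in% c("association", "mirna_sim", "disease_sim", "generic")))
    return("unknown factorization role")
  TRUE
})

#' Real-valued confidence score matrix
#'
#' The pipeline output \eqn{C}: one real confidence score per
#' miRNA-disease pair, same shape and labels as the input
#' [AssociationMatrix]. Higher scores mean the pair is a more likely
#' association.
#'
#' @slot scores finite numeric matrix with miRNA rownames and disease
#'   colnames.
#' @seealso [grmdaScore()], [rankForDisease()], [writeScores()]
#' @export
setClass("ScoreMatrix", representation(scores = "matrix"))

setValidity("ScoreMatrix", function(object) {
  s <- object@scores
  if (!is.numeric(s) || !all(is.finite(s))) return("scores must be finite numbers")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    return("score matrix must carry miRNA rownames and disease colnames")
  msg <- .checkLabels(rownames(s), "miRNA")
  if (!is.null(msg)) return(msg)
  msg <- .checkLabels(colnames(s), "disease")
  if (!is.null(msg)) return(msg)
  TRUE
})

#' Cross-validation result
#'
#' Summary of a leave-one-out or repeated k-fold run: the mean AUC over
#' repetitions, its standard deviation (0 for LOOCV), the per-repetition
#' AUC list, and the pooled ROC curve as ordered (FPR, TPR) points running
#' from (0, 0) to (1, 1).
#'
#' @slot auc mean area under the ROC curve, in [0, 1].
#' @slot aucSd standard deviation over repetitions.
#' @slot perRepAucs numeric vector, one AUC per repetition.
#' @slot rocPoints two-column numeric matrix (FPR, TPR), both non-decreasing.
#' @slot nFolds integer number of folds executed per repetition.
#' @slot seed integer seed in force (NA if none).
#' @seealso [loocv()], [kfoldCv()], [writeCvResult()]
#' @export
setClass("CvResult",
         representation(auc = "numeric", aucSd = "numeric",
                        perRepAucs = "numeric", rocPoints = "matrix",
                        nFolds = "integer", seed = "integer"))

setValidity("CvResult", function(object) {
  if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
    return("auc must be a single value in [0, 1]")
  if (length(object@aucSd) != 1L || object@aucSd < 0)
    return("aucSd must be a single non-negative value")
  rp <- object@rocPoints
  if (ncol(rp) != 2L) return("rocPoints must have two columns (FPR, TPR)")
  if (nrow(rp) < 2L) return("rocPoints must hold at least (0,0) and (1,1)")
  if (any(abs(rp[1, ] - 0) > 1e-12) || any(abs(rp[nrow(rp), ] - 1) > 1e-12))
    return("rocPoints must start at (0,0) and end at (1,1)")
  if (is.unsorted(rp[, 1]) || is.unsorted(rp[, 2]))
    return("rocPoints coordinates must be non-decreasing")
  TRUE
})

#' Synthetic data bundle
#'
#' One seeded draw from the synthetic generator: a planted low-rank binary
#' association matrix, a noisy functional-similarity matrix over the miRNA
#' axis (with a zero mask emulating missing functional similarity), a random
#' disease DAG corpus whose placement is correlated with the planted disease
#' factors, and the ground truth (latent factors and the Bernoulli
#' probability matrix).
#'
#' @slot assoc an [AssociationMatrix].
#' @slot fs a [SimilarityMatrix] with role FS.
#' @slot corpus a [DagCorpus] (covers a subset of diseases when
#'   \code{daglessFraction} > 0).
#' @slot truth list with elements \code{X} (miRNA factors), \code{Y}
#'   (disease factors) and \code{P} (probability matrix).
#' @slot seed integer seed used (NA if none).
#' @seealso [makeBundle()], [writeBundle()]
#' @export
setClass("SyntheticBundle",
         representation(assoc = "AssociationMatrix", fs = "SimilarityMatrix",
                        corpus = "DagCorpus", truth = "list", seed = "integer"))
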