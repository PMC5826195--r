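#' Model-1 semantic contributions of a disease's DAG
#'
#' In the first semantic model, a disease D contributes 1 to its own
#' semantic value, and every ancestor term d contributes
#' \eqn{\max_{d' \in children(d)} \Delta \cdot contribution(d')}, so
#' contributions decay geometrically with hop distance from D (terms in the
#' same layer of a chain contribute equally). The semantic value DV is the
#' sum of contributions over T(D).
#'
#' @param dag one disease's DAG descriptor, as returned by [diseaseDag()]:
#'   \code{list(node, nodes, edges)} with \code{edges} a 2-column
#'   (parent, child) matrix.
#' @param delta semantic contribution factor, strictly in (0, 1).
#' @return list with \code{contrib} (named numeric over T(D)) and \code{dv}.
#' @export
#' @examples
#' dag <- list(node = "D", nodes = c("D", "P", "G"),
#'             edges = cbind(parent = c("P", "G"), child = c("D", "P")))
#' contributionModel1(dag, 0.5)
contributionModel1 <- function(dag, delta) {
  stopIfNot(length(delta) == 1L && is.finite(delta) && delta > 0 && delta < 1,
            "delta must lie strictly in (0, 1)")
  nodes <- dag$nodes
  edges <- dag$edges
  contrib <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  contrib[dag$node] <- 1
  if (length(nodes) > 1L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
      directed = TRUE, vertices = data.frame(name = nodes))
    if (!igraph::is_dag(g)) stop("DAG contains a cycle", call. = FALSE)
    # children before parents: reverse of parent->child topological order
    order <- rev(names(igraph::topo_sort(g, mode = "out")))
    for (v in order) {
      if (v == dag$node) next
      kids <- edges[edges[, 1] == v, 2]
      kids <- kids[!is.na(contrib[kids])]
      if (length(kids) == 0L)
        stop("node ", v, " in T(D) has no descendant path to the disease node",
             call. = FALSE)
      contrib[v] <- delta * max(contrib[kids])
    }
  }
  list(contrib = contrib, dv = sum(contrib))
}

#' Model-2 semantic contributions over a DAG corpus
#'
#' The second semantic model weights each term t by its specificity across
#' the corpus: \eqn{-\log(\#DAGs\ containing\ t / \#diseases)} with the
#' natural logarithm, where the denominator counts the diseases possessing
#' a DAG in the corpus. The weight of a term is the same for every disease;
#' a disease's semantic value DV2 sums the weights over its own T(D). Terms
#' present in every DAG contribute 0.
#'
#' @param corpus a [DagCorpus].
#' @return named list, one element per covered disease, each
#'   \code{list(contrib, dv)} with \code{contrib} restricted to that
#'   disease's T(D).
#' @export
contributionModel2 <- function(corpus) {
  nDis <- length(corpus@diseases)
  stopIfNot(nDis >= 1L, "corpus is empty")
  counts <- table(unlist(lapply(corpus@dags, `[[`, "nodes")))
  weight <- -log(as.numeric(counts) / nDis)
  names(weight) <- names(counts)
  out <- lapply(corpus@dags, function(dag) {
    contrib <- weight[dag$nodes]
    names(contrib) <- dag$nodes
    list(contrib = contrib, dv = sum(contrib))
  })
  names(out) <- names(corpus@dags)
  out
}

#' Semantic similarity of two contribution maps
#'
#' The shared-term contributions of both diseases, summed and normalized by
#' the two semantic values: terms in the overlap of the two DAGs count
#' their contribution from each side, so identical DAGs score 1 and
#' disjoint DAGs score 0. Both maps must come from the same model and
#' corpus.
#'
#' @param ci,cj contribution maps (\code{list(contrib, dv)}) from
#'   [contributionModel1()] or [contributionModel2()].
#' @return similarity in [0, 1].
#' @export
pairwiseSemanticSimilarity <- function(ci, cj) {
  den <- ci$dv + cj$dv
  if (den == 0)
    stop("both contribution maps are empty (DV sums to 0)", call. = FALSE)
  shared <- intersect(names(ci$contrib), names(cj$contrib))
  if (length(shared) == 0L) return(0)
  num <- sum(ci$contrib[shared]) + sum(cj$contrib[shared])
  min(1, num / den)
}

#' Build both disease semantic similarity matrices and the semantic mask
#'
#' Fills SS1 (model 1, decay factor \code{delta}) and SS2 (model 2,
#' corpus-frequency weighting) over the full disease axis of the
#' association matrix. Pairs where either disease lacks a DAG get 0; the
#' diagonal is 1 for DAG-covered diseases and 0 otherwise. The semantic
#' mask marks the pairs treated as "having semantic similarity" — those
#' with SS1 > 0, i.e. sharing at least one ancestor term — which is where
#' the integrated disease similarity uses the semantic average rather than
#' the Gaussian kernel.
#'
#' @param corpus a [DagCorpus]; may cover a subset of \code{allDiseases}.
#' @param delta semantic contribution factor for model 1.
#' @param allDiseases ordered disease labels of the association matrix.
#' @return list with [SimilarityMatrix] elements \code{ss1}, \code{ss2}
#'   (roles SS1/SS2) and \code{mask}, a labelled logical matrix.
#' @export
buildSemanticMatrices <- function(corpus, delta, allDiseases) {
  msg <- .checkLabels(allDiseases, "disease")
  if (!is.null(msg)) stop(msg, call. = FALSE)
  n <- length(allDiseases)
  ss1 <- matrix(0, n, n, dimnames = list(allDiseases, allDiseases))
  ss2 <- ss1
  covered <- intersect(allDiseases, corpus@diseases)
  if (length(covered) > 0L) {
    maps1 <- lapply(covered, function(d)
      contributionModel1(corpus@dags[[d]], delta))
    names(maps1) <- covered
    maps2 <- contributionModel2(corpus)[covered]
    for (a in seq_along(covered)) {
      for (b in seq_len(a - 1L)) {
        i <- covered[a]; j <- covered[b]
        ss1[i, j] <- ss1[j, i] <- pairwiseSemanticSimilarity(maps1[[i]], maps1[[j]])
        # model-2 DV can be 0 for a root-level disease (all its terms are
        # shared by every DAG); such a pair carries no model-2 signal
        ss2[i, j] <- ss2[j, i] <-
          if (maps2[[i]]$dv + maps2[[j]]$dv == 0) 0
          else pairwiseSemanticSimilarity(maps2[[i]], maps2[[j]])
      }
      # a disease with a DAG is identical to itself under both models
      ss1[covered[a], covered[a]] <- 1
      ss2[covered[a], covered[a]] <- 1
    }
  }
  mask <- ss1 > 0
  list(ss1 = SimilarityMatrix(ss1, role = "SS1"),
       ss2 = SimilarityMatrix(ss2, role = "SS2"),
       mask = mask)
}
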