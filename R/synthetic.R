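#' Random disease DAG corpus
#'
#' Builds a rooted tree of the given depth and branching factor (padding
#' with extra leaves when there are more diseases than nodes), assigns each
#' DAG-bearing disease to a distinct node, and leaves a configurable
#' fraction of diseases without a DAG so the Gaussian-kernel fallback of
#' the integrated disease similarity is exercised. Acyclic by construction.
#'
#' @param nDiseases number of diseases (labels \code{d1..dn} unless
#'   \code{diseases} is given).
#' @param depth tree depth (>= 1; the root is depth 0).
#' @param branching children per internal node (>= 1).
#' @param daglessFraction fraction of diseases left without a DAG
#'   (default 0.2).
#' @param seed integer seed (NULL/NA = ambient RNG).
#' @param diseases optional explicit disease labels.
#' @return a [DagCorpus] covering the DAG-bearing diseases.
#' @export
#' @examples
#' corpusDiseases(randomDagCorpus(5, daglessFraction = 0, seed = 1))
randomDagCorpus <- function(nDiseases, depth = 3, branching = 4,
                            daglessFraction = 0.2, seed = NULL,
                            diseases = NULL) {
  stopIfNot(nDiseases >= 1L, "nDiseases must be at least 1")
  stopIfNot(depth >= 1L && branching >= 1L, "depth and branching must be >= 1")
  stopIfNot(daglessFraction >= 0 && daglessFraction < 1,
            "daglessFraction must lie in [0, 1)")
  if (is.null(diseases)) diseases <- paste0("d", seq_len(nDiseases))
  withSeed(seed, {
    # rooted tree: node t1 is the root; level l has branching^l nodes
    child <- character(0)
    parent <- character(0)
    level <- list("t1")
    nid <- 1L
    for (l in seq_len(depth)) {
      nxt <- character(0)
      for (par in level[[l]]) {
        for (b in seq_len(branching)) {
          nid <- nid + 1L
          node <- paste0("t", nid)
          child <- c(child, node)
          parent <- c(parent, par)
          nxt <- c(nxt, node)
        }
      }
      level[[l + 1L]] <- nxt
    }
    allNodes <- paste0("t", seq_len(nid))
    nWithDag <- nDiseases - floor(daglessFraction * nDiseases)
    dagless <- if (nWithDag < nDiseases)
      sort(sample(seq_len(nDiseases), nDiseases - nWithDag)) else integer(0)
    withDag <- setdiff(seq_len(nDiseases), dagless)
    # pad with extra leaves under random non-root nodes if tree is too small
    while (length(allNodes) < length(withDag)) {
      nid <- nid + 1L
      node <- paste0("t", nid)
      par <- sample(allNodes, 1)
      child <- c(child, node)
      parent <- c(parent, par)
      allNodes <- c(allNodes, node)
    }
    assigned <- sample(allNodes, length(withDag))
    buildDagCorpus(child = child, parent = parent,
                   diseases = diseases[withDag], nodes = assigned)
  })
}

#' Planted low-rank binary association matrix
#'
#' Draws non-negative latent factors X (nm x g) and Y (nd x g) from a
#' gamma(shape 2, scale 1) distribution — so the product is non-negative
#' and right-skewed, mimicking sparse association data — forms the
#' probability matrix \eqn{P \propto X Y^T} rescaled to the requested mean
#' density (capped at 1), and samples each cell independently as
#' Bernoulli(P).
#'
#' @param nm,nd numbers of miRNAs and diseases.
#' @param g latent rank, g <= min(nm, nd).
#' @param density target mean of P, in (0, 1).
#' @param seed integer seed (NULL/NA = ambient RNG).
#' @param X,Y optional externally drawn latent factors (nm x g, nd x g);
#'   when supplied only the Bernoulli sampling consumes randomness.
#' @param shape,scale gamma parameters for the latent factors.
#' @return list with \code{assoc} (an [AssociationMatrix]) and \code{truth}
#'   (list of X, Y, P).
#' @export
plantedAssociationMatrix <- function(nm, nd, g, density, seed = NULL,
                                     X = NULL, Y = NULL,
                                     shape = 2, scale = 1) {
  stopIfNot(g >= 1L && g <= min(nm, nd), "g must lie in [1, min(nm, nd)]")
  stopIfNot(density > 0 && density < 1, "density must lie in (0, 1)")
  withSeed(seed, {
    if (is.null(X)) X <- matrix(stats::rgamma(nm * g, shape, scale = scale), nm, g)
    if (is.null(Y)) Y <- matrix(stats::rgamma(nd * g, shape, scale = scale), nd, g)
    stopIfNot(nrow(X) == nm && ncol(X) == g, "X must be nm x g")
    stopIfNot(nrow(Y) == nd && ncol(Y) == g, "Y must be nd x g")
    P <- tcrossprod(X, Y)
    P <- P * (density / mean(P))
    P <- pmin(P, 1)
    a <- matrix(stats::rbinom(nm * nd, 1, P), nm, nd,
                dimnames = list(paste0("m", seq_len(nm)),
                                paste0("d", seq_len(nd))))
    list(assoc = AssociationMatrix(a), truth = list(X = X, Y = Y, P = P))
  })
}

# Cosine similarity of the rows of a non-negative factor matrix.
.cosineRows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  s <- tcrossprod(x / nrm)
  s[s > 1] <- 1
  s[s < 0] <- 0
  diag(s) <- 1
  s
}

#' Generate a complete synthetic input bundle
#'
#' One seeded draw of everything the pipeline consumes: a planted low-rank
#' association matrix; a functional similarity matrix equal to the cosine
#' similarity of the true miRNA factors plus symmetric noise (clipped to
#' [0, 1], unit diagonal), with a random fraction of off-diagonal entries
#' zeroed to exercise the kernel fallback; and a random DAG corpus whose
#' node placement is correlated with the disease factors — diseases whose
#' nodes share a parent draw their factors around a common group mean — so
#' the semantic similarity is informative about the planted structure.
#'
#' @param nm,nd,g,density as in [plantedAssociationMatrix()]; defaults
#'   nm = 100, nd = 60, g = 3, density = 0.05.
#' @param fsNoise standard deviation of the additive noise on the
#'   functional similarity (default 0.1).
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @param daglessFraction fraction of diseases without a DAG (default 0.2).
#' @param fsZeroFraction fraction of off-diagonal FS entries zeroed
#'   (default 0.3).
#' @param depth,branching DAG tree shape (defaults 3 and 4).
#' @param groupShape gamma shape of the shared parent-group component of
#'   each DAG-covered disease's latent factors, in [0, 2]. The factors are
#'   the sum of a group draw gamma(groupShape, 1) shared by sibling
#'   diseases and an individual draw gamma(2 - groupShape, 1), so the
#'   marginal stays gamma(2, 1) while siblings correlate with
#'   groupShape / 2 (default 1, i.e. correlation 0.5).
#' @return a [SyntheticBundle].
#' @export
#' @examples
#' b <- makeBundle(nm = 20, nd = 12, seed = 1)
#' b
makeBundle <- function(nm = 100, nd = 60, g = 3, density = 0.05,
                       fsNoise = 0.1, seed = NULL, daglessFraction = 0.2,
                       fsZeroFraction = 0.3, depth = 3, branching = 4,
                       groupShape = 1) {
  stopIfNot(fsNoise >= 0, "fsNoise must be non-negative")
  stopIfNot(fsZeroFraction >= 0 && fsZeroFraction < 1,
            "fsZeroFraction must lie in [0, 1)")
  stopIfNot(groupShape >= 0 && groupShape <= 2,
            "groupShape must lie in [0, 2]")
  withSeed(seed, {
    diseases <- paste0("d", seq_len(nd))
    corpus <- randomDagCorpus(nd, depth = depth, branching = branching,
                              daglessFraction = daglessFraction,
                              diseases = diseases)
    # disease factors: siblings in the DAG share a group mean
    parentOf <- vapply(corpus@diseases, function(d) {
      dag <- corpus@dags[[d]]
      i <- which(dag$edges[, "child"] == dag$node)
      if (length(i) == 1L) dag$edges[i, "parent"] else "root"
    }, character(1))
    groups <- unique(parentOf)
    # additive gamma decomposition keeps the marginal at gamma(2, 1)
    mu <- matrix(if (groupShape > 0)
                   stats::rgamma(length(groups) * g, groupShape, scale = 1)
                 else 0,
                 length(groups), g, dimnames = list(groups, NULL))
    Y <- matrix(stats::rgamma(nd * g, 2, scale = 1), nd, g)
    covered <- match(corpus@diseases, diseases)
    own <- matrix(if (groupShape < 2)
                    stats::rgamma(length(covered) * g, 2 - groupShape, scale = 1)
                  else 0,
                  length(covered), g)
    Y[covered, ] <- mu[parentOf, , drop = FALSE] + own
    X <- matrix(stats::rgamma(nm * g, 2, scale = 1), nm, g)
    planted <- plantedAssociationMatrix(nm, nd, g, density, X = X, Y = Y)
    # functional similarity: noisy cosine similarity of the true factors
    fsv <- .cosineRows(X)
    if (fsNoise > 0) {
      e <- matrix(stats::rnorm(nm * nm, 0, fsNoise), nm, nm)
      fsv <- fsv + (e + t(e)) / 2
      fsv[fsv < 0] <- 0
      fsv[fsv > 1] <- 1
      diag(fsv) <- 1
    }
    if (fsZeroFraction > 0 && nm > 1) {
      pairs <- which(upper.tri(fsv), arr.ind = TRUE)
      drop <- pairs[sample(nrow(pairs), floor(fsZeroFraction * nrow(pairs))), ,
                    drop = FALSE]
      fsv[drop] <- 0
      fsv[drop[, c(2, 1), drop = FALSE]] <- 0
    }
    fs <- SimilarityMatrix(fsv, labels = mirnaNames(planted$assoc), role = "FS")
    new("SyntheticBundle", assoc = planted$assoc, fs = fs, corpus = corpus,
        truth = planted$truth,
        seed = as.integer(if (is.null(seed)) NA else seed))
  })
}

#' Write a synthetic bundle in the package's file dialects
#'
#' Emits \code{associations.tsv} (pair list), \code{mirna_similarity.tsv}
#' (labelled square), \code{dag_edges.tsv} (child, parent),
#' \code{dag_membership.tsv} (disease, node) and \code{truth.json} into a
#' directory, exactly as the loaders read them.
#'
#' @param bundle a [SyntheticBundle].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory path.
#' @export
writeBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeAssociations(bundle@assoc, file.path(dir, "associations.tsv"))
  writeSimilarity(bundle@fs, file.path(dir, "mirna_similarity.tsv"))
  edges <- unique(do.call(rbind, lapply(bundle@corpus@dags, `[[`, "edges")))
  writeLines(paste(edges[, "child"], edges[, "parent"], sep = "\t"),
             file.path(dir, "dag_edges.tsv"))
  writeLines(paste(names(bundle@corpus@membership), bundle@corpus@membership,
                   sep = "\t"),
             file.path(dir, "dag_membership.tsv"))
  jsonlite::write_json(list(X = bundle@truth$X, Y = bundle@truth$Y,
                            P = bundle@truth$P,
                            seed = if (is.na(bundle@seed)) NULL else bundle@seed),
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
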