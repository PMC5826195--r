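#' Read known miRNA-disease association pairs
#'
#' Reads a two-column tab-separated file of (miRNA id, disease id) pairs,
#' one pair per line with no header, and encodes it as a binary
#' [AssociationMatrix]: entry (i, j) is 1 iff the pair appears at least
#' once. Axis orderings follow first appearance in the file; duplicate
#' pairs collapse silently. Identifier matching is exact, case-sensitive
#' text.
#'
#' @param path path to the TSV file.
#' @return an [AssociationMatrix].
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("m1\td1", "m1\td2", "m2\td2"), tf)
#' as.matrix(loadAssociations(tf))
loadAssociations <- function(path) {
  stopIfNot(file.exists(path), "association file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  stopIfNot(length(lines) >= 1L, "association file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop("malformed association row (expected 2 tab-separated columns) at line ",
         bad[1], " of ", path, call. = FALSE)
  m <- vapply(parts, `[`, character(1), 1L)
  d <- vapply(parts, `[`, character(1), 2L)
  mids <- unique(m)
  dids <- unique(d)
  a <- matrix(0, length(mids), length(dids), dimnames = list(mids, dids))
  a[cbind(match(m, mids), match(d, dids))] <- 1
  AssociationMatrix(a)
}

#' Read a labelled square similarity matrix
#'
#' Reads a tab-separated file with a header row of labels and a leading
#' label column; header labels must equal row labels in the same order.
#' The matrix must be numeric, symmetric to within 1e-9 and lie in [0, 1].
#'
#' @param path path to the TSV file.
#' @param role role tag for the result (default \code{"FS"}).
#' @return a [SimilarityMatrix].
#' @seealso [writeSimilarity()]
#' @export
loadSimilarity <- function(path, role = "FS") {
  stopIfNot(file.exists(path), "similarity file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot(nrow(df) == ncol(df),
            "similarity matrix must be square; got ", nrow(df), " x ", ncol(df))
  stopIfNot(identical(rownames(df), colnames(df)),
            "similarity header labels must equal row labels in the same order")
  v <- as.matrix(df)
  if (!is.numeric(v) || anyNA(v))
    stop("similarity matrix contains non-numeric cells", call. = FALSE)
  if (max(abs(v - t(v))) > 1e-9)
    stop("similarity matrix is asymmetric beyond 1e-9", call. = FALSE)
  if (min(v) < 0 || max(v) > 1)
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  SimilarityMatrix(v, role = role)
}

#' Write a similarity matrix
#'
#' Emits the labelled square TSV dialect read by [loadSimilarity()].
#'
#' @param sim a [SimilarityMatrix].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSimilarity <- function(sim, path) {
  v <- as.matrix(sim)
  out <- cbind(label = rownames(v), format(v, digits = 15, trim = TRUE,
                                           scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("", colnames(v)))
  invisible(path)
}

#' Read a corpus of disease DAGs
#'
#' The global term DAG is given as a child-to-parent edge list (two
#' tab-separated columns, no header); the membership file maps each disease
#' label to its own node (two columns, no header). For each disease,
#' \eqn{T(D)} is its node plus all ancestors reachable via parent edges, and
#' \eqn{E(D)} is the induced parent-to-child edge set. Cycles in the edge
#' file are rejected.
#'
#' @param edgesPath TSV of (child, parent) node pairs.
#' @param membershipPath TSV of (disease label, node) pairs.
#' @return a [DagCorpus].
#' @export
loadDagCorpus <- function(edgesPath, membershipPath) {
  stopIfNot(file.exists(edgesPath), "DAG edge file not found: ", edgesPath)
  stopIfNot(file.exists(membershipPath),
            "DAG membership file not found: ", membershipPath)
  readPairs <- function(path, what) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad) > 0L)
      stop("malformed ", what, " row at line ", bad[1], " of ", path,
           call. = FALSE)
    cbind(vapply(parts, `[`, character(1), 1L),
          vapply(parts, `[`, character(1), 2L))
  }
  edges <- readPairs(edgesPath, "edge")          # (child, parent)
  members <- readPairs(membershipPath, "membership")
  stopIfNot(nrow(members) >= 1L, "membership file is empty: ", membershipPath)
  buildDagCorpus(child = edges[, 1], parent = edges[, 2],
                 diseases = members[, 1], nodes = members[, 2])
}

# Assemble a DagCorpus from vectors of child->parent links and the
# disease -> node mapping. Shared by loadDagCorpus and the synthetic
# generator.
buildDagCorpus <- function(child, parent, diseases, nodes) {
  stopIfNot(!anyDuplicated(diseases), "duplicate disease in membership")
  # the edge file defines the term vocabulary
  terms <- unique(c(child, parent))
  unknown <- setdiff(nodes, terms)
  if (length(unknown) > 0L)
    stop("disease mapped to unknown node: ", unknown[1], call. = FALSE)
  # parent edges stored as child -> parent for ancestor closure
  g <- igraph::graph_from_data_frame(
    data.frame(from = child, to = parent, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = terms))
  if (!igraph::is_dag(g))
    stop("DAG edge file contains a cycle", call. = FALSE)
  dags <- vector("list", length(diseases))
  names(dags) <- diseases
  for (i in seq_along(diseases)) {
    node <- nodes[i]
    anc <- names(igraph::subcomponent(g, node, mode = "out"))  # node + ancestors
    keep <- child %in% anc & parent %in% anc
    e <- if (any(keep)) cbind(parent = parent[keep], child = child[keep])
         else matrix(character(0), 0, 2, dimnames = list(NULL, c("parent", "child")))
    dags[[i]] <- list(node = node, nodes = anc, edges = e)
  }
  membership <- stats::setNames(nodes, diseases)
  new("DagCorpus", diseases = diseases, membership = membership,
      dags = dags, terms = terms)
}

#' Write known associations as a pair list
#'
#' Emits the two-column (miRNA id, disease id) TSV read by
#' [loadAssociations()], one known association per line, in row-major
#' matrix order. Note a pair list cannot represent miRNAs or diseases with
#' no associations, nor an axis ordering differing from first appearance.
#'
#' @param assoc an [AssociationMatrix] with at least one association.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAssociations <- function(assoc, path) {
  a <- as.matrix(assoc)
  idx <- which(t(a) == 1, arr.ind = TRUE)  # row-major order
  stopIfNot(nrow(idx) >= 1L, "no known associations to write")
  writeLines(paste(rownames(a)[idx[, 2]], colnames(a)[idx[, 1]], sep = "\t"),
             path)
  invisible(path)
}

#' Write a score matrix as a long-format TSV
#'
#' One row per (miRNA, disease, score) triple, sorted by disease (in the
#' matrix's column order) and then by descending score, ties broken by
#' miRNA label. A header line \code{mirna\tdisease\tscore} is written.
#' Values are written with enough digits that a round trip through
#' [readScores()] reproduces them to 1e-9.
#'
#' @param scores a [ScoreMatrix].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeScores <- function(scores, path) {
  s <- as.matrix(scores)
  if (!all(is.finite(s))) stop("scores must be finite", call. = FALSE)
  rows <- do.call(rbind, lapply(colnames(s), function(d) {
    ord <- order(-s[, d], rownames(s))
    data.frame(mirna = rownames(s)[ord], disease = d, score = s[ord, d],
               stringsAsFactors = FALSE)
  }))
  rows$score <- sprintf("%.12g", rows$score)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("mirna\tdisease\tscore", con)
  writeLines(paste(rows$mirna, rows$disease, rows$score, sep = "\t"), con)
  invisible(path)
}

#' Read a long-format score TSV back into a ScoreMatrix
#'
#' Axis orderings follow first appearance in the file.
#'
#' @param path path written by [writeScores()].
#' @return a [ScoreMatrix].
#' @export
readScores <- function(path) {
  stopIfNot(file.exists(path), "score file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  stopIfNot(all(c("mirna", "disease", "score") %in% colnames(df)),
            "score file must have columns mirna, disease, score")
  mids <- unique(df$mirna)
  dids <- unique(df$disease)
  s <- matrix(NA_real_, length(mids), length(dids),
              dimnames = list(mids, dids))
  s[cbind(match(df$mirna, mids), match(df$disease, dids))] <- df$score
  if (anyNA(s)) stop("score file does not cover every pair", call. = FALSE)
  ScoreMatrix(s)
}

#' Write a cross-validation result as JSON
#'
#' Serializes auc, aucSd, perRepAucs, nFolds and seed; ROC points can be
#' written separately as a TSV via \code{rocPath}.
#'
#' @param cv a [CvResult].
#' @param path output JSON path.
#' @param rocPath optional path for a two-column (FPR, TPR) TSV.
#' @return invisibly, \code{path}.
#' @export
writeCvResult <- function(cv, path, rocPath = NULL) {
  obj <- list(auc = cv@auc, auc_std = cv@aucSd,
              per_rep_aucs = cv@perRepAucs, n_folds = cv@nFolds,
              seed = if (is.na(cv@seed)) NULL else cv@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(rocPath)) {
    utils::write.table(data.frame(FPR = cv@rocPoints[, 1], TPR = cv@rocPoints[, 2]),
                       rocPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
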