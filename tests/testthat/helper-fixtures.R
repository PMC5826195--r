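# Shared fixtures, all built in code.

# Four-node toy ontology: G is the root, P its child, D1 and D2 siblings
# under P; each of the four diseases sits at its own node.
toyCorpus <- function() {
  ed <- withr::local_tempfile(lines = c("P\tG", "D1\tP", "D2\tP"),
                              .local_envir = parent.frame())
  mem <- withr::local_tempfile(lines = c("G\tG", "P\tP", "D1\tD1", "D2\tD2"),
                               .local_envir = parent.frame())
  loadDagCorpus(ed, mem)
}

# 3 miRNAs x 2 diseases with profiles [1,0], [0,1], [1,1].
toyAssoc <- function() {
  AssociationMatrix(matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE),
                    paste0("m", 1:3), paste0("d", 1:2))
}

# Brute-force Mann-Whitney AUC: mean pairwise credit with ties at 0.5.
bruteAuc <- function(tests, candidates) {
  mean(outer(tests, candidates, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Random small DAG corpus expressed through the loader (chains and diamonds).
randomSmallCorpus <- function(nNodes, seed) {
  set.seed(seed)
  # node i (> 1) gets 1-2 parents among nodes 1..i-1: acyclic by construction
  child <- character(0)
  parent <- character(0)
  for (i in 2:nNodes) {
    for (p in sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))) {
      child <- c(child, paste0("n", i))
      parent <- c(parent, paste0("n", p))
    }
  }
  ed <- tempfile()
  writeLines(paste(child, parent, sep = "\t"), ed)
  mem <- tempfile()
  writeLines(paste(paste0("dis", seq_len(nNodes)), paste0("n", seq_len(nNodes)),
                   sep = "\t"), mem)
  loadDagCorpus(ed, mem)
}

# Null model: scatter the association entries uniformly over the matrix
# (same number of 1s, no planted structure left for any scorer to recover).
shuffleAssociations <- function(assoc, seed) {
  a <- as.matrix(assoc)
  set.seed(seed)
  an <- matrix(sample(c(a)), nrow(a), ncol(a), dimnames = dimnames(a))
  AssociationMatrix(an)
}
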