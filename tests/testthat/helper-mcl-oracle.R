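# Independent reference MCL, written straight from the canonical algorithm
# description: expansion = matrix power, inflation = entrywise power with
# column re-normalization, iterated to (near-)idempotency with no pruning;
# clusters are the weakly connected components of the limit matrix's
# support.  Used only as a test oracle.
oracleMcl <- function(network, inflation, expansion = 2, maxIter = 1000,
                      tol = 1e-12) {
  genes <- networkGenes(network)
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  e <- networkEdges(network)
  for (r in seq_len(nrow(e))) {
    i <- match(e$gene_a[r], genes)
    j <- match(e$gene_b[r], genes)
    A[i, j] <- A[j, i] <- e$weight[r]
  }
  for (i in seq_len(n)) {
    m <- max(A[i, ])
    A[i, i] <- if (m > 0) m else 1
  }
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(maxIter)) {
    Mold <- M
    Mx <- M
    for (p in seq_len(expansion - 1)) Mx <- Mx %*% M
    Mx <- Mx^inflation
    M <- sweep(Mx, 2, colSums(Mx), "/")
    if (max(abs(M - Mold)) < tol) break
  }
  supp <- (M > 1e-7) | t(M > 1e-7)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(supp, mode = "max"))$membership
  unname(split(genes, comp))
}
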