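#' Construct a GeneNetwork from an edge table
#'
#' @param genes character vector of node symbols.
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{weight}; pairs are canonicalized and sorted.
#' @param droppedGenes genes excluded from the node set, kept for reporting.
#' @return a \linkS4class{GeneNetwork}.
#' @export
GeneNetwork <- function(genes, edges = NULL, droppedGenes = character(0)) {
  if (is.null(edges))
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        weight = numeric(0))
  new("GeneNetwork", genes = as.character(genes),
      edges = orderEdgeTable(edges), droppedGenes = droppedGenes)
}

#' Build a thresholded Pearson co-expression network
#'
#' Every gene pair with at least \code{minPairs} pairwise-complete
#' observations and \code{|r| >= threshold} (or \code{r >= threshold} in
#' signed mode) becomes an edge weighted by \code{|r|}.  Constant
#' (zero-variance) genes stay in the node set but get no edges.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param threshold correlation cutoff in [0, 1] (default 0.6).
#' @param signed if TRUE threshold the signed correlation instead of its
#'   absolute value; weights remain \code{|r|}.
#' @param minPairs minimum pairwise-complete observations per retained pair.
#' @return a \linkS4class{GeneNetwork} over all dataset genes.
#' @export
correlationNetwork <- function(dataset, threshold = 0.6, signed = FALSE,
                               minPairs = 3L) {
  v <- exprsValues(dataset)
  genes <- rownames(v)
  if (anyDuplicated(genes))
    toxsigValidationError("duplicate gene symbols; run mergeDuplicateGenes first")
  suppressWarnings(r <- stats::cor(t(v), use = "pairwise.complete.obs"))
  obs <- crossprod(t(!is.na(v)) * 1)         # pairwise-complete counts
  sds <- apply(v, 1L, stats::sd, na.rm = TRUE)
  constant <- !is.na(sds) & sds == 0
  if (any(constant))
    warning(sprintf("%d constant gene(s) excluded from edges: %s",
                    sum(constant),
                    paste(utils::head(genes[constant], 5L), collapse = ", ")))
  keep <- upper.tri(r) & !is.na(r) & obs >= minPairs
  keep <- keep & (if (signed) r >= threshold else abs(r) >= threshold)
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                      weight = pmin(abs(r[idx]), 1))
  GeneNetwork(genes, edges)
}

#' Intersect co-expression networks into one consensus network
#'
#' An edge is kept only if it is present in every input network; its
#' consensus weight is the arithmetic mean of the per-network weights
#' (absolute correlations).  The consensus node set is the set of genes
#' incident to at least one kept edge; harmonized genes left without any
#' consensus edge are reported in \code{\link{droppedGenes}} (or kept as
#' isolated nodes with \code{keepIsolated = TRUE}).
#'
#' @param networks list of >= 1 \linkS4class{GeneNetwork}s over a harmonized
#'   gene universe.
#' @param keepIsolated keep edgeless harmonized genes in the node set.
#' @return a \linkS4class{GeneNetwork}.
#' @export
consensusNetwork <- function(networks, keepIsolated = FALSE) {
  if (length(networks) == 0L)
    toxsigValidationError("consensusNetwork needs at least one network")
  keys <- lapply(networks, function(n) edgeKeys(networkEdges(n)))
  shared <- Reduce(intersect, keys)
  first <- networkEdges(networks[[1L]])
  kept <- first[match(shared, keys[[1L]]), c("gene_a", "gene_b"), drop = FALSE]
  w <- vapply(networks,
              function(n) networkEdges(n)$weight[match(shared, edgeKeys(networkEdges(n)))],
              numeric(length(shared)))
  kept$weight <- if (length(shared)) rowMeans(matrix(w, nrow = length(shared))) else numeric(0)
  universe <- Reduce(intersect, lapply(networks, networkGenes))
  incident <- unique(c(kept$gene_a, kept$gene_b))
  isolated <- setdiff(universe, incident)
  if (keepIsolated)
    GeneNetwork(sort(c(incident, isolated)), kept)
  else
    GeneNetwork(sort(incident), kept, droppedGenes = sort(isolated))
}

#' Read / write a network edge-list TSV (gene_a, gene_b, weight)
#' @param path file path.
#' @param genes optional node universe; defaults to genes seen in edges.
#' @return a \linkS4class{GeneNetwork}.
#' @export
readEdgeTsv <- function(path, genes = NULL) {
  e <- utils::read.delim(path, colClasses = c("character", "character", "numeric"))
  GeneNetwork(genes %||% sort(unique(c(e$gene_a, e$gene_b))), e)
}

#' @rdname readEdgeTsv
#' @param network a \linkS4class{GeneNetwork}.
#' @export
writeEdgeTsv <- function(network, path) {
  utils::write.table(networkEdges(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
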