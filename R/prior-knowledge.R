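#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated: name, description, members.  The
#' source family is guessed from the set name prefix (\code{HALLMARK} vs
#' anything else -> kegg-like) unless given.
#'
#' @param path file path.
#' @param family optional character vector of families per set.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, family = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (is.null(family))
    family <- ifelse(grepl("^HALLMARK", names(sets)), "hallmark", "kegg")
  new("GeneSetCollection", sets = sets, family = family)
}

#' @rdname readGmt
#' @param collection a \linkS4class{GeneSetCollection}.
#' @export
writeGmt <- function(collection, path) {
  lines <- vapply(seq_along(collection@sets), function(i) {
    paste(c(names(collection@sets)[i], collection@family[i],
            collection@sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a typed interaction edge-list TSV
#'
#' Columns: node_a, type_a, node_b, type_b, association_class.
#'
#' @param path file path.
#' @return an \linkS4class{InteractionGraph}.
#' @export
readInteractionTsv <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  nodes <- unique(rbind(data.frame(id = d$node_a, type = d$type_a),
                        data.frame(id = d$node_b, type = d$type_b)))
  new("InteractionGraph", nodes = nodes,
      edges = d[, c("node_a", "node_b", "association_class")])
}

#' @rdname readInteractionTsv
#' @param graph an \linkS4class{InteractionGraph}.
#' @export
writeInteractionTsv <- function(graph, path) {
  typeOf <- setNames(graph@nodes$type, graph@nodes$id)
  d <- data.frame(node_a = graph@edges$node_a,
                  type_a = typeOf[graph@edges$node_a],
                  node_b = graph@edges$node_b,
                  type_b = typeOf[graph@edges$node_b],
                  association_class = graph@edges$association_class)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# igraph over the mechanistic/marker subgraph only.
mechanisticSubgraph <- function(graph) {
  e <- graph@edges[graph@edges$association_class == "mechanistic/marker", ,
                   drop = FALSE]
  igraph::graph_from_data_frame(e[, c("node_a", "node_b")], directed = FALSE,
                                vertices = graph@nodes$id)
}

#' Encode prior-knowledge features for a gene universe
#'
#' One row per gene: a z-scored 0/1 membership column per gene set,
#' followed by three log-scaled topology features (degree, betweenness
#' centrality, closeness centrality) of the gene in the
#' mechanistic/marker-class interaction subgraph.  At reference scale (50
#' hallmark + 186 KEGG-like sets) this yields 239-dimensional vectors.
#' Genes absent from the graph get the transform of zero; constant
#' membership columns cannot be z-scored and are set to zero with a
#' warning.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param graph an \linkS4class{InteractionGraph}.
#' @param geneUniverse character vector of gene symbols.
#' @param normalizedBetweenness divide betweenness by its maximum attainable
#'   value (default TRUE).
#' @return numeric matrix, genes x (sets + 3) features.
#' @export
encodePriorFeatures <- function(collection, graph, geneUniverse,
                                normalizedBetweenness = TRUE) {
  if (length(geneUniverse) == 0L)
    toxsigValidationError("empty gene universe")
  sets <- collection@sets
  member <- matrix(0, nrow = length(geneUniverse), ncol = length(sets),
                   dimnames = list(geneUniverse, names(sets)))
  for (j in seq_along(sets))
    member[geneUniverse %in% sets[[j]], j] <- 1
  sds <- apply(member, 2L, stats::sd)
  constant <- sds == 0
  if (any(constant))
    warning(sprintf("%d constant membership column(s) set to zero", sum(constant)))
  member[, !constant] <- scale(member[, !constant, drop = FALSE])
  member[, constant] <- 0

  g <- mechanisticSubgraph(graph)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  if (normalizedBetweenness && n > 2)
    btw <- btw / ((n - 1) * (n - 2) / 2)
  # closeness is computed within components (reachable vertices only);
  # isolated nodes, where it is undefined, get 0
  clo <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  clo[!is.finite(clo)] <- 0
  topo <- matrix(0, nrow = length(geneUniverse), ncol = 3L,
                 dimnames = list(geneUniverse,
                                 c("degree", "betweenness", "closeness")))
  present <- intersect(geneUniverse, igraph::V(g)$name)
  topo[present, "degree"] <- deg[present]
  topo[present, "betweenness"] <- btw[present]
  topo[present, "closeness"] <- clo[present]
  topo <- log1p(topo)   # log-scaling with +1 offset so zero maps to zero
  cbind(member, topo)
}

#' Convert prior features into per-gene prior scores
#'
#' Projects the feature matrix onto two principal components, partitions the
#' genes with K-means (default K = 3, multiple restarts at a fixed seed),
#' and scores each gene by its Euclidean distance to its assigned centroid
#' in the 2-D plane: genes far from their centroid contribute most to the
#' prior-knowledge space.  Genes are ranked by that distance (ties broken
#' lexicographically by symbol) and the final score is
#' \eqn{(n - rank + 1)/n}, so the top gene scores 1.0 and the bottom one
#' \eqn{1/n}.
#'
#' @param features matrix from \code{\link{encodePriorFeatures}}.
#' @param k number of K-means clusters (default 3).
#' @param seed RNG seed for the K-means restarts.
#' @param standardizeAll re-standardize every column (including the
#'   log-scaled topology block) before the PCA; default FALSE keeps the
#'   topology block on its log scale.
#' @return a \linkS4class{PriorScoreTable}.
#' @export
computePriorScores <- function(features, k = 3L, seed = 1L,
                               standardizeAll = FALSE) {
  n <- nrow(features)
  if (n < k) toxsigValidationError("k = %d exceeds the %d genes", k, n)
  if (any(!is.finite(features)))
    toxsigValidationError("features must be finite")
  if (standardizeAll) {
    sds <- apply(features, 2L, stats::sd)
    features[, sds > 0] <- scale(features[, sds > 0, drop = FALSE])
    features[, sds == 0] <- 0
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  xy <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(xy, centers = min(k, nrow(unique(xy))), nstart = 10L,
                      iter.max = 100L)
  dist2 <- rowSums((xy - km$centers[km$cluster, , drop = FALSE])^2)
  raw <- sqrt(dist2)
  genes <- rownames(features)
  o <- order(-raw, genes)            # descending distance, ties by symbol
  tab <- data.frame(gene = genes[o], rank = seq_len(n),
                    score = (n - seq_len(n) + 1) / n, raw = raw[o])
  new("PriorScoreTable", table = tab)
}

#' Read / write a prior score TSV (gene, rank, score)
#' @param path file path.
#' @return a \linkS4class{PriorScoreTable}.
#' @export
readPriorTsv <- function(path) {
  new("PriorScoreTable", table = utils::read.delim(path))
}

#' @rdname readPriorTsv
#' @param priors a \linkS4class{PriorScoreTable}.
#' @export
writePriorTsv <- function(priors, path) {
  utils::write.table(priors@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
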