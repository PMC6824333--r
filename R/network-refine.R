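#' Create an MCLConfig
#'
#' @param inflation granularity parameter in the recommended range
#'   1.2--5.0 (default 3.3).
#' @param expansion matrix-power per iteration (default 2).
#' @param pruneThreshold entries below this are zeroed after inflation
#'   (default 1e-5).
#' @param maxIterations iteration cap (default 200).
#' @param convergenceTolerance max column-wise change declaring convergence
#'   (default 1e-8).
#' @param selfLoopWeight fixed self-loop weight, or \code{NA} (default) to
#'   use each node's maximum incident edge weight.
#' @return a validated \linkS4class{MCLConfig}.
#' @export
mclConfig <- function(inflation = 3.3, expansion = 2L, pruneThreshold = 1e-5,
                      maxIterations = 200L, convergenceTolerance = 1e-8,
                      selfLoopWeight = NA_real_) {
  new("MCLConfig", inflation = inflation, expansion = as.integer(expansion),
      pruneThreshold = pruneThreshold, maxIterations = as.integer(maxIterations),
      convergenceTolerance = convergenceTolerance,
      selfLoopWeight = as.numeric(selfLoopWeight))
}

#' Re-weight network edges with prior scores
#'
#' Mean mode (default): \eqn{S_{new}(A,B) = S(A,B) (P(A)+P(B))/2}.
#' Product mode: \eqn{S_{new}(A,B) = S(A,B) P(A) P(B)}.  With all priors at
#' 1 the network is unchanged; weights stay in [0, 1].
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param priors a \linkS4class{PriorScoreTable} covering every network gene.
#' @param mode \code{"mean"} or \code{"product"}.
#' @return a re-weighted \linkS4class{GeneNetwork}.
#' @export
reweightEdges <- function(network, priors, mode = c("mean", "product")) {
  mode <- match.arg(mode)
  p <- priorScores(priors)
  missing <- setdiff(networkGenes(network), names(p))
  if (length(missing))
    toxsigValidationError("no prior score for network gene(s): %s",
                          paste(utils::head(missing, 10L), collapse = ", "))
  e <- networkEdges(network)
  pa <- p[e$gene_a]
  pb <- p[e$gene_b]
  e$weight <- if (mode == "mean") e$weight * (pa + pb) / 2
              else e$weight * pa * pb
  GeneNetwork(networkGenes(network), e, droppedGenes(network))
}

# --- Markov Cluster Algorithm ----------------------------------------------

# Entrywise inflation followed by column re-normalization; zero columns
# (possible after aggressive pruning) fall back to a self-loop.
mclInflate <- function(M, inflation, pruneThreshold) {
  M <- M^inflation
  M[M < pruneThreshold] <- 0
  cs <- colSums(M)
  dead <- cs == 0
  if (any(dead)) {
    M[cbind(which(dead), which(dead))] <- 1
    cs[dead] <- 1
  }
  sweep(M, 2L, cs, "/")
}

# Column-stochastic transition matrix with self-loops.
mclTransition <- function(network, selfLoopWeight = NA_real_) {
  genes <- networkGenes(network)
  n <- length(genes)
  e <- networkEdges(network)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  if (nrow(e)) {
    i <- match(e$gene_a, genes)
    j <- match(e$gene_b, genes)
    A[cbind(i, j)] <- e$weight
    A[cbind(j, i)] <- e$weight
  }
  loop <- if (is.na(selfLoopWeight)) apply(A, 1L, max) else
    rep(selfLoopWeight, n)
  loop[loop == 0] <- 1          # isolated nodes self-attract
  diag(A) <- loop
  sweep(A, 2L, colSums(A), "/")
}

# Read the clustering off a (near-)idempotent MCL iterate.  Attractors are
# nodes with positive diagonal mass; attractors sharing any node's support
# are merged into one attractor system; every node joins the system holding
# the largest share of its column mass (ties -> lowest system index).
mclInterpret <- function(M, genes) {
  n <- length(genes)
  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  sub <- M[attractors, , drop = FALSE]
  # merge attractors co-supporting any column (overlapping systems)
  adj <- (sub > 0) %*% t(sub > 0) > 0
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "max"))$membership
  # re-index systems by their lowest attractor index for determinism
  sysIndex <- match(comp, unique(comp))
  mass <- rowsum(sub, sysIndex)
  best <- apply(mass, 2L, function(col) which(col == max(col))[1L])
  unassigned <- colSums(sub) == 0
  if (any(unassigned)) {
    # non-converged columns: follow the largest entry instead
    top <- apply(M[, unassigned, drop = FALSE], 2L, which.max)
    near <- vapply(top, function(r) {
      hit <- which(sub[, r] > 0)
      if (length(hit)) sysIndex[hit[1L]] else NA_integer_
    }, integer(1))
    best[unassigned] <- ifelse(is.na(near), max(sysIndex) + seq_along(near), near)
  }
  split(genes, best)
}

#' Partition a weighted gene network with the Markov Cluster Algorithm
#'
#' Builds the column-stochastic transition matrix (self-loops added),
#' then alternates expansion (matrix power) with inflation (entrywise
#' power, pruning of small entries, column re-normalization) until the
#' maximum column-wise change falls below the tolerance or the iteration
#' cap is hit.  Clusters are read from the attractor structure of the
#' limit; isolated genes become singletons.  Deterministic for a fixed
#' input.
#'
#' @param network a nonempty \linkS4class{GeneNetwork}.
#' @param config an \linkS4class{MCLConfig}.
#' @return a \linkS4class{GeneClustering}; clusters are ordered by
#'   decreasing size (ties by first member symbol).
#' @export
mclCluster <- function(network, config = mclConfig()) {
  genes <- networkGenes(network)
  if (length(genes) == 0L) toxsigValidationError("empty network")
  validObject(config)
  M <- mclTransition(network, config@selfLoopWeight)
  converged <- FALSE
  for (it in seq_len(config@maxIterations)) {
    Mexp <- M
    for (p in seq_len(config@expansion - 1L)) Mexp <- Mexp %*% M
    Mnew <- mclInflate(Mexp, config@inflation, config@pruneThreshold)
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < config@convergenceTolerance) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge in %d iterations; interpreting current iterate",
                    config@maxIterations))
  cl <- mclInterpret(M, genes)
  first <- vapply(cl, function(g) min(g), character(1))
  cl <- cl[order(-lengths(cl), first)]
  names(cl) <- NULL
  new("GeneClustering", clusters = lapply(cl, sort), converged = converged)
}

#' Clustering quality: mass fraction and efficiency
#'
#' \code{mass_fraction} is the fraction of total edge weight falling within
#' clusters.  \code{efficiency} is a weighted clustering performance score:
#' with edge weights in [0, 1] and absent pairs counted as weight 0,
#' \deqn{efficiency = [\sum_{intra} w + \sum_{inter} (1 - w)] / {n \choose 2},}
#' i.e. the fraction of gene pairs "handled well" -- heavy pairs kept
#' together and light/absent pairs kept apart.  Both are 1 for the
#' connected-components clustering of a disconnected union of cliques and
#' decrease with misplaced mass.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param clustering a \linkS4class{GeneClustering} covering the network
#'   genes.
#' @return list with \code{mass_fraction} and \code{efficiency}.
#' @export
clusteringQuality <- function(network, clustering) {
  genes <- networkGenes(network)
  member <- clusterAssignments(clustering)
  if (!all(genes %in% names(member)))
    toxsigValidationError("clustering does not cover all network genes")
  e <- networkEdges(network)
  n <- length(genes)
  total <- sum(e$weight)
  intra <- member[e$gene_a] == member[e$gene_b]
  wIntra <- sum(e$weight[intra])
  massFraction <- if (total > 0) wIntra / total else 1
  nPairs <- n * (n - 1) / 2
  intraPairs <- sum(vapply(clusterSizes(clustering),
                           function(s) s * (s - 1) / 2, numeric(1)))
  efficiency <- if (nPairs > 0)
    (wIntra + (nPairs - intraPairs) - (total - wIntra)) / nPairs else 1
  list(mass_fraction = massFraction, efficiency = efficiency)
}

#' Summary statistics of a clustering
#' @param clustering a \linkS4class{GeneClustering}.
#' @return list with \code{n_genes}, \code{n_clusters}, \code{mean_size}
#'   (\code{n_genes / n_clusters}), \code{min_size}, \code{max_size}.
#' @export
clusteringSummary <- function(clustering) {
  s <- clusterSizes(clustering)
  list(n_genes = sum(s), n_clusters = length(s),
       mean_size = sum(s) / length(s),
       min_size = if (length(s)) min(s) else NA_integer_,
       max_size = if (length(s)) max(s) else NA_integer_)
}

#' Scan MCL inflation values
#'
#' Runs \code{\link{mclCluster}} at each inflation value and tabulates
#' cluster counts, quality measures and size summaries, supporting the
#' choice of granularity.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param inflations numeric vector of inflation values.
#' @param config base \linkS4class{MCLConfig}; its inflation is overridden.
#' @return data.frame with one row per inflation value.
#' @export
inflationScan <- function(network, inflations, config = mclConfig()) {
  if (length(inflations) == 0L)
    toxsigValidationError("no inflation values supplied")
  rows <- lapply(inflations, function(inf) {
    cfg <- config
    cfg@inflation <- inf
    cl <- mclCluster(network, cfg)
    q <- clusteringQuality(network, cl)
    s <- clusteringSummary(cl)
    data.frame(inflation = inf, n_clusters = s$n_clusters,
               mass_fraction = q$mass_fraction, efficiency = q$efficiency,
               mean_size = s$mean_size, min_size = s$min_size,
               max_size = s$max_size, converged = cl@converged)
  })
  do.call(rbind, rows)
}

#' Read / write a cluster file (one line per cluster, tab-separated symbols)
#' @param path file path.
#' @return a \linkS4class{GeneClustering}.
#' @export
readClusters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  new("GeneClustering", clusters = strsplit(lines, "\t", fixed = TRUE),
      converged = TRUE)
}

#' @rdname readClusters
#' @param clustering a \linkS4class{GeneClustering}.
#' @export
writeClusters <- function(clustering, path) {
  writeLines(vapply(clusters(clustering), paste, character(1), collapse = "\t"),
             path)
  invisible(path)
}
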