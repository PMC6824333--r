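# Score table carrying the given scores verbatim (a ceiling entry keeps
# the rank-1-scores-1 invariant without rescaling the genes under test).
priorOf <- function(scores) {
  s <- c(scores, "__TOP__" = 1.0)
  o <- order(-s, names(s))
  new("PriorScoreTable",
      table = data.frame(gene = names(s)[o], rank = seq_along(s),
                         score = unname(s[o]), raw = unname(s[o])))
}

test_that("edge re-weighting follows the mean- and product-prior rules", {
  net <- GeneNetwork(c("A", "B"),
                     data.frame(gene_a = "A", gene_b = "B", weight = 0.8))
  pri <- new("PriorScoreTable",
             table = data.frame(gene = c("A", "B"), rank = 1:2,
                                score = c(1.0, 0.5), raw = c(2, 1)))
  expect_equal(networkEdges(reweightEdges(net, pri))$weight, 0.6)
  expect_equal(networkEdges(reweightEdges(net, pri, mode = "product"))$weight,
               0.4)
  # unit priors leave the network unchanged
  unit <- new("PriorScoreTable",
              table = data.frame(gene = c("A", "B"), rank = 1:2,
                                 score = c(1, 1), raw = c(1, 1)))
  expect_equal(networkEdges(reweightEdges(net, unit))$weight, 0.8)
  # a missing prior is an error naming the gene
  expect_error(reweightEdges(GeneNetwork(c("A", "B", "C"),
                                         networkEdges(net)), pri),
               "C", class = "toxsig_validation_error")
})

test_that("re-weighting is monotone in the priors and stays in [0, 1]", {
  net <- randomNetwork(10, p = 0.5, seed = 4)
  genes <- networkGenes(net)
  set.seed(4)
  base <- setNames(runif(length(genes), 0.1, 0.45), genes)
  w0 <- networkEdges(reweightEdges(net, priorOf(base)))$weight
  for (g in genes[1:3]) {
    raised <- base
    raised[g] <- raised[g] + 0.5
    w1 <- networkEdges(reweightEdges(net, priorOf(raised)))$weight
    expect_true(all(w1 >= w0 - 1e-12))
  }
  expect_true(all(w0 >= 0 & w0 <= 1))
})

test_that("MCL separates disconnected cliques and isolates singletons", {
  cl4 <- function(prefix) {
    p <- t(combn(paste0(prefix, 1:4), 2))
    data.frame(gene_a = p[, 1], gene_b = p[, 2], weight = 1)
  }
  net <- GeneNetwork(c(paste0("A", 1:4), paste0("B", 1:4), "LONE"),
                     rbind(cl4("A"), cl4("B")))
  cl <- mclCluster(net)
  parts <- canonicalPartition(clusters(cl))
  expect_equal(parts, canonicalPartition(list(paste0("A", 1:4),
                                              paste0("B", 1:4), "LONE")))
  single <- mclCluster(GeneNetwork("ONLY"))
  expect_equal(clusters(single), list("ONLY"))
})

test_that("every inflation step preserves column-stochasticity", {
  net <- randomNetwork(15, p = 0.3, seed = 6)
  M <- toxsig:::mclTransition(net)
  expect_equal(unname(colSums(M)), rep(1, 15), tolerance = 1e-12)
  for (i in 1:5) {
    M <- toxsig:::mclInflate(M %*% M, 3.3, 1e-5)
    expect_equal(unname(colSums(M)), rep(1, 15), tolerance = 1e-9)
  }
})

test_that("MCL partitions match an independent reference implementation", {
  for (s in 1:20) {
    net <- randomNetwork(sample(20:50, 1), p = 0.12, seed = 300 + s)
    for (inf in c(2.0, 3.3)) {
      got <- canonicalPartition(clusters(mclCluster(net, mclConfig(inflation = inf))))
      want <- canonicalPartition(oracleMcl(net, inflation = inf))
      expect_equal(got, want,
                   label = sprintf("seed %d inflation %.1f", s, inf))
    }
  }
})

test_that("clustering is always a partition of the network genes", {
  for (s in 1:5) {
    net <- randomNetwork(25, p = 0.15, seed = 40 + s)
    cl <- mclCluster(net)
    members <- unlist(clusters(cl))
    expect_setequal(members, networkGenes(net))
    expect_equal(length(members), length(networkGenes(net)))
    expect_true(all(clusterSizes(cl) >= 1))
  }
})

test_that("mass fraction and efficiency behave at the extremes and on a toy graph", {
  cl4 <- function(prefix) {
    p <- t(combn(paste0(prefix, 1:4), 2))
    data.frame(gene_a = p[, 1], gene_b = p[, 2], weight = 1)
  }
  net <- GeneNetwork(c(paste0("A", 1:4), paste0("B", 1:4)),
                     rbind(cl4("A"), cl4("B")))
  comp <- new("GeneClustering",
              clusters = list(paste0("A", 1:4), paste0("B", 1:4)),
              converged = TRUE)
  q <- clusteringQuality(net, comp)
  expect_equal(q$mass_fraction, 1.0)
  expect_equal(q$efficiency, 1.0)
  singletons <- new("GeneClustering",
                    clusters = as.list(networkGenes(net)), converged = TRUE)
  expect_equal(clusteringQuality(net, singletons)$mass_fraction, 0.0)

  # 6-node toy: weights enumerated by hand
  toy <- GeneNetwork(sprintf("N%d", 1:6),
                     data.frame(gene_a = c("N1", "N1", "N2", "N4", "N4", "N3"),
                                gene_b = c("N2", "N3", "N3", "N5", "N6", "N4"),
                                weight = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.2)))
  two <- new("GeneClustering",
             clusters = list(c("N1", "N2", "N3"), c("N4", "N5", "N6")),
             converged = TRUE)
  qt <- clusteringQuality(toy, two)
  # intra = 0.9 + 0.8 + 0.7 + 0.6 + 0.5 = 3.5; total = 3.7
  expect_equal(qt$mass_fraction, 3.5 / 3.7)
  # pairs = 15, intra pairs = 6, inter mass = 0.2
  expect_equal(qt$efficiency, (3.5 + (15 - 6) - 0.2) / 15)
})

test_that("inflation scan tabulates granularity that rises with inflation", {
  cfg <- simulationConfig(nGenes = 60L, nSamples = c(80L, 80L, 80L),
                          moduleSizes = rep(15L, 4L),
                          withinModuleCorrelation = 0.85,
                          nInformativeModules = 0L, missingRate = 0,
                          seed = 17L)
  tr <- generateExpressionTriplet(cfg)
  cons <- consensusNetwork(lapply(harmonizeOrthologs(tr$datasets),
                                  correlationNetwork))
  scan <- inflationScan(cons, c(1.4, 2.0, 3.3, 5.0))
  expect_equal(nrow(scan), 4)
  expect_true(!is.unsorted(scan$n_clusters))       # weakly increasing
  expect_equal(scan$mean_size,
               length(networkGenes(cons)) / scan$n_clusters)
  one <- inflationScan(cons, 3.3)
  expect_equal(nrow(one), 1)
})

test_that("cluster files round-trip", {
  cl <- new("GeneClustering",
            clusters = list(c("A", "B"), c("C"), c("D", "E", "F")),
            converged = TRUE)
  f <- withr::local_tempfile(fileext = ".txt")
  writeClusters(cl, f)
  expect_equal(clusters(readClusters(f)), clusters(cl))
})
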