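test_that("feature vectors have one column per gene set plus 3 topology features", {
  b <- defaultBundle()
  genes <- rownames(b@datasets[[1]])
  f <- encodePriorFeatures(b@geneSets, b@interactions, genes)
  expect_equal(ncol(f), length(geneSets(b@geneSets)) + 3)
  expect_equal(nrow(f), length(genes))
  # membership columns are z-scored: mean 0, sd 1 (unless constant)
  memb <- f[, seq_len(length(geneSets(b@geneSets))), drop = FALSE]
  nonconst <- apply(memb, 2, sd) > 0
  expect_equal(unname(colMeans(memb[, nonconst])),
               rep(0, sum(nonconst)), tolerance = 1e-12)
  expect_equal(unname(apply(memb[, nonconst], 2, sd)),
               rep(1, sum(nonconst)), tolerance = 1e-12)
})

test_that("genes absent from sets and graph get the transform of zero", {
  sets <- new("GeneSetCollection", sets = list(S1 = c("A", "B")),
              family = "kegg")
  graph <- new("InteractionGraph",
               nodes = data.frame(id = c("A", "B", "C", "D", "CHEM1"),
                                  type = c("gene", "gene", "gene", "gene",
                                           "chemical")),
               edges = data.frame(node_a = c("A", "B"), node_b = "CHEM1",
                                  association_class = "mechanistic/marker"))
  f <- encodePriorFeatures(sets, graph, c("A", "B", "C", "D"))
  expect_identical(unname(f["C", c("degree", "betweenness", "closeness")]),
                   c(0, 0, 0))
  expect_identical(f["C", ], f["D", ])   # both fully absent -> same vector
  expect_lt(f["C", "S1"], 0)             # z-score of a 0 in a 0/1 column
})

test_that("topology features match hand-computed centralities on a path graph", {
  # path A - B - C - D among genes
  graph <- new("InteractionGraph",
               nodes = data.frame(id = c("A", "B", "C", "D"), type = "gene"),
               edges = data.frame(node_a = c("A", "B", "C"),
                                  node_b = c("B", "C", "D"),
                                  association_class = "mechanistic/marker"))
  sets <- new("GeneSetCollection", sets = list(), family = character(0))
  f <- encodePriorFeatures(sets, graph, c("A", "B", "C", "D"))
  # degree: 1, 2, 2, 1
  expect_equal(unname(f[, "degree"]), log1p(c(1, 2, 2, 1)))
  # betweenness (B and C each carry 2 shortest paths), normalized by
  # (n-1)(n-2)/2 = 3
  expect_equal(unname(f[, "betweenness"]), log1p(c(0, 2, 2, 0) / 3))
  # normalized closeness: (n-1) / sum of distances
  expect_equal(unname(f[, "closeness"]),
               log1p(c(3 / 6, 3 / 4, 3 / 4, 3 / 6)))
})

test_that("non-mechanistic associations are excluded from topology", {
  graph <- new("InteractionGraph",
               nodes = data.frame(id = c("A", "B", "CHEM1"),
                                  type = c("gene", "gene", "chemical")),
               edges = data.frame(node_a = c("A", "B"), node_b = "CHEM1",
                                  association_class = c("mechanistic/marker",
                                                        "therapeutic")))
  sets <- new("GeneSetCollection", sets = list(), family = character(0))
  f <- encodePriorFeatures(sets, graph, c("A", "B"))
  expect_gt(f["A", "degree"], 0)
  expect_equal(unname(f["B", "degree"]), 0)
})

test_that("prior scores are the rank bijection onto {1/n, ..., 1}", {
  b <- defaultBundle()
  genes <- rownames(b@datasets[[1]])
  f <- encodePriorFeatures(b@geneSets, b@interactions, genes)
  pri <- computePriorScores(f, seed = 3L)
  tab <- priorTable(pri)
  n <- nrow(tab)
  expect_equal(sort(tab$score), (1:n) / n)
  expect_equal(tab$score[tab$rank == 1], 1.0)
  expect_equal(min(tab$score), 1 / n)
  # scores decrease with rank and raw distances are non-increasing
  o <- order(tab$rank)
  expect_true(all(diff(tab$score[o]) < 0))
  expect_true(all(diff(tab$raw[o]) <= 1e-12))
})

test_that("prior scoring is equivariant under gene relabeling", {
  set.seed(31)
  f <- matrix(rnorm(40 * 6), nrow = 40,
              dimnames = list(sprintf("G%02d", 1:40), paste0("f", 1:6)))
  p1 <- priorScores(computePriorScores(f, seed = 5L))
  perm <- sample(nrow(f))
  f2 <- f[perm, ]
  p2 <- priorScores(computePriorScores(f2, seed = 5L))
  expect_equal(p2[names(p1)], p1)
})

test_that("identical feature rows still yield a full score ladder via tie-breaks", {
  f <- matrix(1, nrow = 6, ncol = 4,
              dimnames = list(sprintf("G%d", 1:6), paste0("f", 1:4)))
  pri <- computePriorScores(f, k = 3L, seed = 1L)
  tab <- priorTable(pri)
  expect_equal(sort(tab$score), (1:6) / 6)
  expect_identical(tab$gene, sort(tab$gene))   # lexicographic tie-break
  expect_error(computePriorScores(f[1:2, ], k = 3L),
               class = "toxsig_validation_error")
})

test_that("informative genes earn higher prior scores under annotation bias", {
  b <- defaultBundle()   # pathwayEnrichmentBias = 5
  genes <- rownames(b@datasets[[1]])
  f <- encodePriorFeatures(b@geneSets, b@interactions, genes)
  pri <- priorScores(computePriorScores(f, seed = 2L))
  info <- genes %in% b@truth$informativeGenes
  expect_gt(mean(pri[genes[info]]), mean(pri[genes[!info]]))
})

test_that("GMT and interaction TSV round-trips preserve structure", {
  b <- defaultBundle()
  fg <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(b@geneSets, fg)
  back <- readGmt(fg)
  expect_identical(names(geneSets(back)), names(geneSets(b@geneSets)))
  expect_identical(geneSets(back), geneSets(b@geneSets))

  fi <- withr::local_tempfile(fileext = ".tsv")
  writeInteractionTsv(b@interactions, fi)
  gback <- readInteractionTsv(fi)
  expect_equal(nrow(gback@edges), nrow(b@interactions@edges))
  # the TSV carries edges, so only nodes with at least one edge survive
  expect_true(all(gback@nodes$id[gback@nodes$type == "gene"] %in%
                    b@interactions@nodes$id[b@interactions@nodes$type == "gene"]))
})
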