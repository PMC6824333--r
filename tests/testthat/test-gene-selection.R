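test_that("quota allocation reproduces proportional shares with caps", {
  q <- allocateQuota(c(A = 0.60, B = 0.55), c(A = 2000L, B = 2000L), 1000L)
  expect_identical(q, c(A = 522L, B = 478L))
  q2 <- allocateQuota(c(A = 0.60, B = 0.55), c(A = 520L, B = 2000L), 1000L)
  expect_identical(q2, c(A = 520L, B = 480L))
  # one cluster takes everything
  expect_identical(allocateQuota(c(A = 0.7), c(A = 1500L), 1000L),
                   c(A = 1000L))
  # not enough genes overall: allocate all, with a warning
  expect_warning(q3 <- allocateQuota(c(A = 0.6, B = 0.4),
                                     c(A = 30L, B = 40L), 100L))
  expect_identical(q3, c(A = 30L, B = 40L))
  # all-zero accuracies fall back to size-proportional
  expect_warning(q4 <- allocateQuota(c(A = 0, B = 0), c(A = 60L, B = 40L),
                                     50L), "zero")
  expect_identical(q4, c(A = 30L, B = 20L))
})

test_that("quota allocation matches a brute-force oracle on random instances", {
  set.seed(77)
  for (i in 1:200) {
    k <- sample(2:10, 1)
    nm <- paste0("c", seq_len(k))
    acc <- setNames(round(runif(k, 0, 1), 3), nm)
    sizes <- setNames(sample(1:80, k, replace = TRUE), nm)
    total <- sample(seq_len(max(sum(sizes), 2L)), 1)
    got <- suppressWarnings(allocateQuota(acc, sizes, total))
    want <- suppressWarnings(oracleAllocate(acc, sizes, total))
    expect_identical(got, want, label = sprintf("instance %d", i))
    expect_equal(sum(got), min(total, sum(sizes)))
    expect_true(all(got <= sizes))
  }
})

test_that("quota allocation is invariant under uniform accuracy rescaling", {
  acc <- c(A = 0.6, B = 0.3, C = 0.9)
  sizes <- c(A = 40L, B = 40L, C = 40L)
  expect_identical(allocateQuota(acc, sizes, 60L),
                   allocateQuota(acc * 10, sizes, 60L))
})

test_that("cluster CV accuracy is at chance for label-independent genes", {
  set.seed(9)
  m <- matrix(rnorm(12 * 80), nrow = 12,
              dimnames = list(sprintf("G%02d", 1:12), sprintf("S%02d", 1:80)))
  d <- quickDataset(m)
  lab <- setNames(rep(c("dysregulated", "non_dysregulated"), c(32, 48)),
                  colnames(m))
  rep1 <- rankClusterGenes(d, lab, rownames(m), seed = 5L, nTrees = 300L)
  # majority-class rate is 0.6; allow generous binomial slack at n = 80
  expect_gt(rep1$accuracy, 0.6 - 0.2)
  expect_lt(rep1$accuracy, 0.6 + 0.15)
  expect_error(rankClusterGenes(d, setNames(rep("dysregulated", 80),
                                            colnames(m)), rownames(m)),
               class = "toxsig_validation_error")
})

test_that("a planted informative gene earns the top importance", {
  hits <- vapply(1:10, function(s) {
    set.seed(400 + s)
    m <- matrix(rnorm(10 * 70), nrow = 10,
                dimnames = list(sprintf("G%02d", 1:10), sprintf("S%02d", 1:70)))
    lab <- setNames(sample(c("dysregulated", "non_dysregulated"), 70,
                           replace = TRUE), colnames(m))
    m["G01", lab == "dysregulated"] <- m["G01", lab == "dysregulated"] + 2
    rep1 <- rankClusterGenes(quickDataset(m), lab, rownames(m),
                             seed = s, nTrees = 200L)
    names(which.max(rep1$importance)) == "G01"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("importance is approximately sum-preserved across duplicated genes", {
  set.seed(19)
  m <- matrix(rnorm(6 * 90), nrow = 6,
              dimnames = list(sprintf("G%d", 1:6), sprintf("S%02d", 1:90)))
  lab <- setNames(sample(c("dysregulated", "non_dysregulated"), 90,
                         replace = TRUE), colnames(m))
  m["G1", lab == "dysregulated"] <- m["G1", lab == "dysregulated"] + 2.5
  single <- rankClusterGenes(quickDataset(m), lab, rownames(m),
                             seed = 8L, nTrees = 1000L)
  mdup <- rbind(m, G1b = m["G1", ])
  dup <- rankClusterGenes(quickDataset(mdup), lab, rownames(mdup),
                          seed = 8L, nTrees = 1000L)
  expect_equal(dup$importance[["G1"]] + dup$importance[["G1b"]],
               single$importance[["G1"]], tolerance = 0.35)
})

test_that("assembly takes top-quota genes per cluster with tie-breaks", {
  rep1 <- list(genes = c("A", "B", "C"), accuracy = 0.8,
               importance = c(A = 0.5, B = 0.3, C = 0.1),
               importanceSd = c(A = 0, B = 0, C = 0), seed = 1)
  rep2 <- list(genes = c("D", "E"), accuracy = 0.6,
               importance = c(D = 0.2, E = 0.9),
               importanceSd = c(D = 0, E = 0), seed = 1)
  out <- assembleSignature(list("1" = rep1, "2" = rep2),
                           c("1" = 2L, "2" = 2L))
  expect_identical(out$gene, c("A", "B", "E", "D"))
  expect_identical(out$cluster, c("1", "1", "2", "2"))
  # quota = cluster size returns the whole cluster
  whole <- assembleSignature(list("1" = rep1), c("1" = 3L))
  expect_setequal(whole$gene, c("A", "B", "C"))
  # equal importance resolved by fold stability, then symbol
  rep3 <- list(genes = c("X", "Y"), accuracy = 0.5,
               importance = c(X = 0.4, Y = 0.4),
               importanceSd = c(X = 0.2, Y = 0.05), seed = 1)
  pick <- assembleSignature(list("3" = rep3), c("3" = 1L))
  expect_identical(pick$gene, "Y")
})

test_that("global ranking orders by importance and signs regulation correctly", {
  set.seed(55)
  m <- matrix(rnorm(8 * 80), nrow = 8,
              dimnames = list(sprintf("G%d", 1:8), sprintf("S%02d", 1:80)))
  lab <- setNames(sample(c("dysregulated", "non_dysregulated"), 80,
                         replace = TRUE), colnames(m))
  m["G1", lab == "dysregulated"] <- m["G1", lab == "dysregulated"] + 3
  m["G2", lab == "dysregulated"] <- m["G2", lab == "dysregulated"] - 3
  sig <- globalRanking(quickDataset(m), lab, rownames(m), seed = 2L)
  tab <- signatureTable(sig)
  expect_identical(sort(tab$rank), 1:8)
  expect_identical(tab$regulation[tab$gene == "G1"], "up")
  expect_identical(tab$regulation[tab$gene == "G2"], "down")
  expect_true(all(tab$gene[tab$rank <= 2] %in% c("G1", "G2")))
  one <- globalRanking(quickDataset(m), lab, "G3", seed = 2L)
  expect_equal(signatureTable(one)$rank, 1L)
})

test_that("the strongest planted effect ranks in the top decile of the signature", {
  hits <- vapply(1:10, function(s) {
    set.seed(600 + s)
    m <- matrix(rnorm(20 * 80), nrow = 20,
                dimnames = list(sprintf("G%02d", 1:20), sprintf("S%02d", 1:80)))
    lab <- setNames(sample(c("dysregulated", "non_dysregulated"), 80,
                           replace = TRUE), colnames(m))
    m["G05", lab == "dysregulated"] <- m["G05", lab == "dysregulated"] + 2.5
    sig <- globalRanking(quickDataset(m), lab, rownames(m), seed = s,
                         nTrees = 300L)
    tab <- signatureTable(sig)
    tab$rank[tab$gene == "G05"] <= 2      # top decile of 20
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("signature TSV round-trips", {
  tab <- data.frame(rank = 1:3, gene = c("A", "B", "C"),
                    cluster = c("1", "1", "2"),
                    importance = c(0.5, 0.4, 0.1),
                    regulation = c("up", "down", "up"))
  sig <- new("RankedSignature", table = tab)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSignatureTsv(sig, f)
  expect_equal(signatureTable(readSignatureTsv(f)), tab)
})
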