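# Shared fixture builders.  Everything is generated in code; nothing is
# read from disk.

# Quick ExpressionDataset from a matrix (gene symbols auto-assigned when
# absent).
quickDataset <- function(m, id = "toy") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  ExpressionDataset(m, datasetId = id)
}

# Random weighted graph as a GeneNetwork (edge prob p, weights U(0.1, 1)).
randomNetwork <- function(n, p = 0.25, seed = 1) {
  set.seed(seed)
  genes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < p
  GeneNetwork(genes, data.frame(gene_a = pairs[keep, 1],
                                gene_b = pairs[keep, 2],
                                weight = runif(sum(keep), 0.1, 1)))
}

# The desk-scale default bundle, generated once per test run.
defaultBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateSyntheticBundle(simulationConfig(seed = 42L),
                                        nGroups = 4L)
    cache
  }
})

# Independent largest-remainder + cap-and-redistribute allocation oracle,
# written directly from the allocation rule (not via the package path).
oracleAllocate <- function(acc, sizes, total) {
  if (sum(sizes) <= total) return(setNames(as.integer(sizes), names(sizes)))
  if (all(acc == 0)) acc <- as.numeric(sizes)
  quota <- setNames(integer(length(acc)), names(acc))
  open <- names(acc)
  left <- total
  repeat {
    if (left == 0 || length(open) == 0) break
    w <- acc[open]
    if (sum(w) == 0) w[] <- 1
    share <- left * w / sum(w)
    base <- floor(share)
    frac <- share - base
    extra <- order(-frac, seq_along(frac))[seq_len(left - sum(base))]
    base[extra] <- base[extra] + 1
    capped <- open[base > sizes[open]]
    if (length(capped) == 0) {
      quota[open] <- as.integer(base)
      break
    }
    quota[capped] <- as.integer(sizes[capped])
    left <- left - sum(sizes[capped])
    open <- setdiff(open, capped)
  }
  quota
}

# Canonical form of a partition (list of gene vectors) for set comparison.
canonicalPartition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, "", 1L))]
}
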