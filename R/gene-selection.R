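# Random-forest gene ranking within clusters, accuracy-proportional quota
# allocation, and assembly of the final ranked signature.

# Median-impute remaining missing entries; random forests require complete
# feature matrices and the upstream modules deliberately leave NAs in place.
imputeForModel <- function(x) {
  if (!anyNA(x)) return(x)
  med <- apply(x, 2L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in which(colSums(is.na(x)) > 0))
    x[is.na(x[, j]), j] <- med[j]
  x
}

checkTwoClasses <- function(y) {
  if (length(unique(y)) < 2L)
    toxsigValidationError("both label classes must be present (got only '%s')",
                          unique(as.character(y)))
}

#' Rank a cluster's genes by random-forest importance
#'
#' Trains a random forest restricted to the cluster's genes under
#' stratified k-fold cross-validation.  The report carries the pooled CV
#' accuracy (used downstream as the cluster's quota weight), and per-gene
#' mean-decrease-in-Gini importances averaged over the fold models (with
#' their across-fold sd, used as a tie-break).
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param labels named character vector (sample -> dysregulated /
#'   non_dysregulated) covering the dataset samples.
#' @param clusterGenes nonempty character vector of genes in the cluster.
#' @param nFolds number of CV folds (default 5).
#' @param seed RNG seed (folds and forests).
#' @param nTrees trees per forest (default 500).
#' @return list with \code{accuracy}, \code{importance},
#'   \code{importanceSd}, \code{genes}, \code{seed}.
#' @export
rankClusterGenes <- function(dataset, labels, clusterGenes, nFolds = 5L,
                             seed = 1L, nTrees = 500L) {
  if (length(clusterGenes) == 0L)
    toxsigValidationError("empty cluster")
  missing <- setdiff(clusterGenes, rownames(dataset))
  if (length(missing))
    toxsigValidationError("cluster genes absent from dataset: %s",
                          paste(utils::head(missing, 5L), collapse = ", "))
  y <- factor(labels[colnames(dataset)])
  checkTwoClasses(y)
  x <- imputeForModel(t(exprsValues(dataset)[clusterGenes, , drop = FALSE]))
  folds <- stratifiedFolds(y, nFolds, seed)
  imp <- matrix(0, nrow = length(clusterGenes), ncol = nFolds,
                dimnames = list(clusterGenes, NULL))
  correct <- 0L
  for (f in seq_len(nFolds)) {
    tr <- folds != f
    set.seed(stageSeed(seed, paste0("rf_fold", f)))
    fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                      ntree = nTrees)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
    imp[, f] <- fit$importance[clusterGenes, "MeanDecreaseGini"]
  }
  list(genes = clusterGenes,
       accuracy = correct / length(y),
       importance = rowMeans(imp),
       importanceSd = apply(imp, 1L, stats::sd),
       seed = seed)
}

# Largest-remainder integerization of fractional shares summing to `total`.
largestRemainder <- function(shares, total) {
  fl <- floor(shares)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    extra <- order(-(shares - fl), seq_along(shares))[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Allocate a gene quota across clusters proportional to model accuracy
#'
#' Each cluster's ideal share is \code{total * acc / sum(acc)},
#' integerized by the largest-remainder rule.  A cluster can never owe
#' more genes than it has: capped clusters keep their full size and the
#' excess is redistributed proportionally among the uncapped clusters,
#' iterating until the quota sums to \code{total} or every cluster is
#' exhausted.
#'
#' @param accuracies named nonnegative numeric, cluster -> CV accuracy.
#' @param clusterSizes named integer, cluster -> gene count.
#' @param total requested signature size (>= 1).
#' @return named integer quota per cluster, summing to
#'   \code{min(total, sum(clusterSizes))}.
#' @export
allocateQuota <- function(accuracies, clusterSizes, total) {
  if (total < 1L) toxsigValidationError("total must be >= 1")
  if (any(accuracies < 0)) toxsigValidationError("accuracies must be >= 0")
  cl <- names(accuracies)
  if (is.null(cl) || !setequal(cl, names(clusterSizes)))
    toxsigValidationError("accuracies and clusterSizes must share cluster names")
  clusterSizes <- clusterSizes[cl]
  if (sum(clusterSizes) <= total) {
    if (sum(clusterSizes) < total)
      warning("requested total exceeds available genes; allocating all")
    return(setNames(as.integer(clusterSizes), cl))
  }
  if (all(accuracies == 0)) {
    warning("all accuracies are zero; falling back to size-proportional allocation")
    accuracies <- as.numeric(clusterSizes)
    names(accuracies) <- cl
  }
  quota <- setNames(integer(length(cl)), cl)
  active <- cl
  remaining <- as.integer(total)
  while (remaining > 0L && length(active)) {
    w <- accuracies[active]
    if (sum(w) == 0) w <- rep(1, length(w))  # residual zero-accuracy clusters
    alloc <- setNames(largestRemainder(remaining * w / sum(w), remaining),
                      active)
    over <- active[alloc > clusterSizes[active]]
    if (length(over) == 0L) {
      quota[active] <- alloc
      remaining <- 0L
    } else {
      quota[over] <- as.integer(clusterSizes[over])
      remaining <- remaining - sum(clusterSizes[over])
      active <- setdiff(active, over)
    }
  }
  quota
}

#' Assemble the signature from per-cluster reports and quotas
#'
#' Takes the top-quota genes of each cluster by importance (ties broken by
#' lower across-fold importance sd, then lexicographically) and
#' concatenates them.
#'
#' @param reports list of \code{\link{rankClusterGenes}} reports, named by
#'   cluster.
#' @param quotas named integer quota per cluster
#'   (\code{\link{allocateQuota}} output).
#' @return data.frame with columns \code{gene}, \code{cluster},
#'   \code{importance}.
#' @export
assembleSignature <- function(reports, quotas) {
  pieces <- lapply(names(quotas), function(cl) {
    q <- quotas[[cl]]
    if (q == 0L) return(NULL)
    r <- reports[[cl]]
    if (is.null(r)) toxsigValidationError("no report for cluster %s", cl)
    if (q > length(r$genes))
      toxsigStageError("select", "quota %d exceeds cluster %s size %d",
                       q, cl, length(r$genes))
    o <- order(-r$importance, r$importanceSd, r$genes)[seq_len(q)]
    data.frame(gene = r$genes[o], cluster = cl,
               importance = unname(r$importance[o]))
  })
  out <- do.call(rbind, pieces)
  out[!duplicated(out$gene), , drop = FALSE]
}

#' Globally re-rank an assembled signature with one final random forest
#'
#' Fits a single random forest over all signature genes and orders them by
#' decreasing Gini importance.  Regulation is \code{"up"} when a gene's
#' mean expression in dysregulated samples exceeds its mean in
#' non-dysregulated samples, else \code{"down"}.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param labels named label vector.
#' @param signature character vector of genes, or the data.frame from
#'   \code{\link{assembleSignature}} (its cluster column is carried along).
#' @param seed RNG seed.
#' @param nTrees trees (default 500).
#' @return a \linkS4class{RankedSignature}.
#' @export
globalRanking <- function(dataset, labels, signature, seed = 1L,
                          nTrees = 500L) {
  if (is.data.frame(signature)) {
    genes <- signature$gene
    clusterOf <- setNames(as.character(signature$cluster), genes)
  } else {
    genes <- as.character(signature)
    clusterOf <- setNames(rep(NA_character_, length(genes)), genes)
  }
  if (length(genes) == 0L) toxsigValidationError("empty signature")
  y <- factor(labels[colnames(dataset)])
  checkTwoClasses(y)
  v <- exprsValues(dataset)[genes, , drop = FALSE]
  x <- imputeForModel(t(v))
  set.seed(stageSeed(seed, "rf_global"))
  fit <- randomForest::randomForest(x, y, ntree = nTrees)
  imp <- fit$importance[genes, "MeanDecreaseGini"]
  dys <- intersect(colnames(v), names(labels)[labels == "dysregulated"])
  non <- setdiff(colnames(v), dys)
  up <- rowMeans(v[, dys, drop = FALSE], na.rm = TRUE) >
    rowMeans(v[, non, drop = FALSE], na.rm = TRUE)
  o <- order(-imp, genes)
  tab <- data.frame(rank = seq_along(genes), gene = genes[o],
                    cluster = unname(clusterOf[genes[o]]),
                    importance = unname(imp[o]),
                    regulation = ifelse(up[genes[o]], "up", "down"))
  new("RankedSignature", table = tab)
}

#' Select and rank a gene signature from a clustering
#'
#' Convenience wrapper over \code{\link{rankClusterGenes}},
#' \code{\link{allocateQuota}}, \code{\link{assembleSignature}} and
#' \code{\link{globalRanking}}.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param labels named label vector.
#' @param clustering a \linkS4class{GeneClustering} (genes must exist in
#'   the dataset).
#' @param size requested signature size.
#' @param nFolds CV folds per cluster model.
#' @param seed RNG seed.
#' @param nTrees trees per forest.
#' @return a \linkS4class{RankedSignature}.
#' @export
selectSignature <- function(dataset, labels, clustering, size = 1000L,
                            nFolds = 5L, seed = 1L, nTrees = 500L) {
  cls <- clusters(clustering)
  names(cls) <- as.character(seq_along(cls))
  reports <- lapply(seq_along(cls), function(i) {
    rankClusterGenes(dataset, labels, cls[[i]], nFolds = nFolds,
                     seed = stageSeed(seed, paste0("cluster", i)),
                     nTrees = nTrees)
  })
  names(reports) <- names(cls)
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  sizes <- setNames(lengths(cls), names(cls))
  quotas <- allocateQuota(acc, sizes, size)
  assembled <- assembleSignature(reports, quotas)
  globalRanking(dataset, labels, assembled, seed = seed, nTrees = nTrees)
}

#' Read / write a signature TSV (rank, gene, cluster, importance, regulation)
#' @param path file path.
#' @return a \linkS4class{RankedSignature}.
#' @export
readSignatureTsv <- function(path) {
  new("RankedSignature",
      table = utils::read.delim(path, colClasses = c("integer", "character",
                                                     "character", "numeric",
                                                     "character")))
}

#' @rdname readSignatureTsv
#' @param signature a \linkS4class{RankedSignature}.
#' @export
writeSignatureTsv <- function(signature, path) {
  utils::write.table(signatureTable(signature), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
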