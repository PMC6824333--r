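# Internal helpers shared across the pipeline.

# Structured conditions: validation errors (bad inputs / config) are
# distinguished from stage failures so the command-line driver can map them
# to distinct exit codes.
toxsigValidationError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("toxsig_validation_error", "toxsig_error", "error")))
}

toxsigStageError <- function(stage, msg, ...) {
  stop(errorCondition(sprintf("[stage %s] %s", stage, sprintf(msg, ...)),
                      class = c("toxsig_stage_error", "toxsig_error", "error")))
}

# Deterministic fan-out of one global seed to per-stage seeds.  Kept below
# 2^31 so the result is always a valid R integer.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# Stratified fold assignment: samples of each class are shuffled and dealt
# round-robin so every fold sees both classes whenever possible.
stratifiedFolds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  labels <- as.character(labels)
  folds <- integer(length(labels))
  set.seed(seed)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Canonical unordered gene-pair ordering used by all edge tables.
orderEdgeTable <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

edgeKeys <- function(edges) paste(edges$gene_a, edges$gene_b, sep = "\r")

`%||%` <- function(a, b) if (is.null(a)) b else a
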