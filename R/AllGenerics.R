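# Generics, accessors and show methods for the core classes.

#' @rdname ExpressionDataset-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("datasetId", "ExpressionDataset", function(x) x@datasetId)

#' @rdname ExpressionDataset-class
#' @export
setGeneric("exprsValues", function(x) standardGeneric("exprsValues"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("exprsValues", "ExpressionDataset",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("sampleAnnotations", function(x) standardGeneric("sampleAnnotations"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleAnnotations", "ExpressionDataset",
          function(x) as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("missingFraction", "ExpressionDataset",
          function(x) mean(is.na(exprsValues(x))))

setMethod("show", "ExpressionDataset", function(object) {
  cat(sprintf("ExpressionDataset '%s': %d genes x %d samples (%.1f%% missing)\n",
              object@datasetId, nrow(object), ncol(object),
              100 * missingFraction(object)))
})

#' @rdname GeneNetwork-class
#' @param x a \linkS4class{GeneNetwork}.
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' @rdname GeneNetwork-class
#' @export
setMethod("networkGenes", "GeneNetwork", function(x) x@genes)

#' @rdname GeneNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname GeneNetwork-class
#' @export
setMethod("networkEdges", "GeneNetwork", function(x) x@edges)

#' @rdname GeneNetwork-class
#' @export
setGeneric("isolatedGenes", function(x) standardGeneric("isolatedGenes"))

#' @rdname GeneNetwork-class
#' @export
setMethod("isolatedGenes", "GeneNetwork", function(x) {
  setdiff(x@genes, unique(c(x@edges$gene_a, x@edges$gene_b)))
})

#' @rdname GeneNetwork-class
#' @export
setGeneric("droppedGenes", function(x) standardGeneric("droppedGenes"))

#' @rdname GeneNetwork-class
#' @export
setMethod("droppedGenes", "GeneNetwork", function(x) x@droppedGenes)

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork: %d genes, %d edges (%d isolated, %d dropped)\n",
              length(object@genes), nrow(object@edges),
              length(isolatedGenes(object)), length(object@droppedGenes)))
})

#' @rdname GeneSetCollection-class
#' @param x a \linkS4class{GeneSetCollection}.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setFamily", function(x) standardGeneric("setFamily"))

#' @rdname GeneSetCollection-class
#' @export
setMethod("setFamily", "GeneSetCollection", function(x) x@family)

setMethod("show", "GeneSetCollection", function(object) {
  fam <- table(object@family)
  cat(sprintf("GeneSetCollection: %d sets (%s)\n", length(object@sets),
              paste(sprintf("%s: %d", names(fam), fam), collapse = ", ")))
})

setMethod("show", "InteractionGraph", function(object) {
  ty <- table(object@nodes$type)
  cat(sprintf("InteractionGraph: %s; %d edges\n",
              paste(sprintf("%d %s", ty, names(ty)), collapse = ", "),
              nrow(object@edges)))
})

#' @rdname PriorScoreTable-class
#' @param x a \linkS4class{PriorScoreTable}.
#' @param genes optional gene symbols to look up.
#' @export
setGeneric("priorScores", function(x, genes = NULL) standardGeneric("priorScores"))

#' @rdname PriorScoreTable-class
#' @export
setMethod("priorScores", "PriorScoreTable", function(x, genes = NULL) {
  s <- setNames(x@table$score, x@table$gene)
  if (is.null(genes)) s else s[genes]
})

#' @rdname PriorScoreTable-class
#' @export
setGeneric("priorTable", function(x) standardGeneric("priorTable"))

#' @rdname PriorScoreTable-class
#' @export
setMethod("priorTable", "PriorScoreTable", function(x) x@table)

setMethod("show", "PriorScoreTable", function(object) {
  cat(sprintf("PriorScoreTable: %d genes, scores in (%.4f, 1]\n",
              nrow(object@table), min(object@table$score)))
})

#' @rdname GeneClustering-class
#' @param x a \linkS4class{GeneClustering}.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname GeneClustering-class
#' @export
setMethod("clusters", "GeneClustering", function(x) x@clusters)

#' @rdname GeneClustering-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname GeneClustering-class
#' @export
setMethod("nClusters", "GeneClustering", function(x) length(x@clusters))

#' @rdname GeneClustering-class
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname GeneClustering-class
#' @export
setMethod("clusterSizes", "GeneClustering", function(x) lengths(x@clusters))

#' @rdname GeneClustering-class
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname GeneClustering-class
#' @export
setMethod("clusterAssignments", "GeneClustering", function(x) {
  rep(seq_along(x@clusters), lengths(x@clusters)) |>
    setNames(unlist(x@clusters, use.names = FALSE))
})

setMethod("show", "GeneClustering", function(object) {
  s <- clusterSizes(object)
  cat(sprintf("GeneClustering: %d clusters over %d genes (sizes %s..%s)%s\n",
              length(s), sum(s), if (length(s)) min(s) else 0,
              if (length(s)) max(s) else 0,
              if (isTRUE(object@converged)) "" else " [not converged]"))
})

#' @rdname RankedSignature-class
#' @param x a \linkS4class{RankedSignature}.
#' @export
setGeneric("signatureTable", function(x) standardGeneric("signatureTable"))

#' @rdname RankedSignature-class
#' @export
setMethod("signatureTable", "RankedSignature", function(x) x@table)

#' @rdname RankedSignature-class
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname RankedSignature-class
#' @export
setMethod("signatureGenes", "RankedSignature",
          function(x) x@table$gene[order(x@table$rank)])

setMethod("show", "RankedSignature", function(object) {
  cat(sprintf("RankedSignature: %d genes (%d up, %d down)\n",
              nrow(object@table), sum(object@table$regulation == "up"),
              sum(object@table$regulation == "down")))
})

setMethod("show", "DoseResponseExperiment", function(object) {
  cat(sprintf("DoseResponseExperiment '%s': %d genes, %d samples, doses {%s}\n",
              object@groupId, nrow(object@values), ncol(object@values),
              paste(sort(unique(object@doses)), collapse = ", ")))
})

setMethod("show", "BMDResult", function(object) {
  cat(sprintf("BMDResult: %d genes fitted (%d with BMD), %d treatment groups\n",
              nrow(object@geneTable), sum(!is.na(object@geneTable$bmd)),
              nrow(object@groupTable)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d genes, samples {%s}, %d modules ",
                     "(%d informative), r=%.2f, missing %.0f%%, seed %d\n"),
              object@nGenes, paste(object@nSamples, collapse = ", "),
              length(object@moduleSizes), object@nInformativeModules,
              object@withinModuleCorrelation, 100 * object@missingRate,
              object@seed))
})

setMethod("show", "SyntheticBundle", function(object) {
  cat("SyntheticBundle:\n")
  for (d in object@datasets) show(d)
  show(object@geneSets)
  show(object@interactions)
  cat(sprintf("  %d dose-response groups; %d informative genes\n",
              length(object@doseResponse),
              length(object@truth$informativeGenes)))
})
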