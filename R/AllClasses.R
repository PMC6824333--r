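#' ExpressionDataset: a gene-by-sample expression matrix with annotations
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding log-scale
#' expression intensities (assay \code{"exprs"}, missing values allowed) and
#' per-sample toxicological annotations in \code{colData}: \code{chemical},
#' \code{dose}, \code{duration}, \code{organ}, \code{species} and, optionally,
#' \code{ldh_percent} (in vitro cytotoxicity proxy) or
#' \code{histopathology_grade} (ordinal severity).
#'
#' @slot datasetId single identifying string for the dataset.
#' @export
setClass("ExpressionDataset",
         contains = "SummarizedExperiment",
         representation(datasetId = "character"))

setValidity("ExpressionDataset", function(object) {
  msgs <- character()
  if (length(object@datasetId) != 1L || is.na(object@datasetId))
    msgs <- c(msgs, "datasetId must be a single string")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "an assay named 'exprs' is required")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msgs <- c(msgs, "gene (row) and sample (column) names are required")
  ann <- SummarizedExperiment::colData(object)
  if (all(c("ldh_percent", "histopathology_grade") %in% colnames(ann))) {
    both <- !is.na(ann$ldh_percent) & !is.na(ann$histopathology_grade)
    if (any(both))
      msgs <- c(msgs, "a sample may carry ldh_percent or histopathology_grade, not both")
  }
  if (length(msgs)) msgs else TRUE
})

#' GeneNetwork: an undirected weighted gene graph
#'
#' Nodes are gene symbols; each edge is an unordered gene pair with a weight
#' in [0, 1] (an absolute Pearson correlation, a consensus mean, or a
#' prior-re-weighted score).  Edges are stored canonically with
#' \code{gene_a < gene_b} and sorted lexicographically so that written edge
#' lists are bit-stable.
#'
#' @slot genes character vector of node symbols (may include isolated genes).
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{weight}.
#' @slot droppedGenes genes of the harmonized universe excluded from the node
#'   set (e.g. genes with no consensus edge), reported for transparency.
#' @export
setClass("GeneNetwork",
         representation(genes = "character", edges = "data.frame",
                        droppedGenes = "character"),
         prototype(droppedGenes = character(0)))

setValidity("GeneNetwork", function(object) {
  msgs <- character()
  e <- object@edges
  if (!all(c("gene_a", "gene_b", "weight") %in% colnames(e)))
    return("edges must have columns gene_a, gene_b, weight")
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "gene symbols must be unique")
  if (nrow(e)) {
    if (any(e$gene_a == e$gene_b)) msgs <- c(msgs, "self-loops are not allowed")
    if (any(e$gene_a > e$gene_b)) msgs <- c(msgs, "edges must be ordered gene_a < gene_b")
    if (any(e$weight < 0 | e$weight > 1)) msgs <- c(msgs, "weights must lie in [0, 1]")
    if (!all(c(e$gene_a, e$gene_b) %in% object@genes))
      msgs <- c(msgs, "edges reference genes outside the node set")
    if (anyDuplicated(edgeKeys(e))) msgs <- c(msgs, "duplicate edges")
  }
  if (length(msgs)) msgs else TRUE
})

#' GeneSetCollection: named gene sets tagged by source family
#'
#' @slot sets named list of character vectors (gene symbols).
#' @slot family character vector parallel to \code{sets}, e.g.
#'   \code{"hallmark"} or \code{"kegg"}.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", family = "character"))

setValidity("GeneSetCollection", function(object) {
  msgs <- character()
  if (length(object@sets) != length(object@family))
    msgs <- c(msgs, "family must be parallel to sets")
  if (length(object@sets) && anyDuplicated(names(object@sets)))
    msgs <- c(msgs, "set names must be unique")
  if (length(msgs)) msgs else TRUE
})

#' InteractionGraph: typed chemical--gene--disease association graph
#'
#' Undirected graph over typed nodes with an association-class label per
#' edge.  Only \code{"mechanistic/marker"}-class edges enter prior-knowledge
#' scoring; other classes (e.g. therapeutic) are retained but ignored there.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}
#'   (chemical | gene | disease).
#' @slot edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{association_class}.
#' @export
setClass("InteractionGraph",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("InteractionGraph", function(object) {
  msgs <- character()
  if (!all(c("id", "type") %in% colnames(object@nodes)))
    return("nodes must have columns id, type")
  if (!all(c("node_a", "node_b", "association_class") %in% colnames(object@edges)))
    return("edges must have columns node_a, node_b, association_class")
  if (!all(object@nodes$type %in% c("chemical", "gene", "disease")))
    msgs <- c(msgs, "node types must be chemical, gene or disease")
  if (anyDuplicated(paste(object@nodes$type, object@nodes$id)))
    msgs <- c(msgs, "node ids must be unique within a type")
  if (length(msgs)) msgs else TRUE
})

#' PriorScoreTable: per-gene prior-knowledge scores
#'
#' Ranks every gene of the universe by its contribution to the
#' prior-knowledge space and assigns score (n - rank + 1)/n, so the
#' top-ranked gene scores 1.0 and the bottom one 1/n.
#'
#' @slot table data.frame with columns \code{gene}, \code{rank}, \code{score}
#'   (and \code{raw}, the centroid distance the rank derives from).
#' @export
setClass("PriorScoreTable", representation(table = "data.frame"))

setValidity("PriorScoreTable", function(object) {
  t <- object@table
  msgs <- character()
  if (!all(c("gene", "rank", "score") %in% colnames(t)))
    return("table must have columns gene, rank, score")
  if (nrow(t)) {
    if (any(t$score <= 0 | t$score > 1)) msgs <- c(msgs, "scores must lie in (0, 1]")
    o <- order(t$rank)
    if (abs(t$score[o][1] - 1) > 1e-12) msgs <- c(msgs, "rank-1 gene must score 1.0")
    if (is.unsorted(rev(t$score[o]))) msgs <- c(msgs, "scores must decrease with rank")
    if (anyDuplicated(t$gene)) msgs <- c(msgs, "genes must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' MCLConfig: Markov Cluster Algorithm parameters
#'
#' @slot inflation entrywise-power granularity parameter, > 1
#'   (recommended range 1.2--5.0; default 3.3).
#' @slot expansion integer matrix-power, >= 2.
#' @slot pruneThreshold entries below this are zeroed after each inflation.
#' @slot maxIterations iteration cap.
#' @slot convergenceTolerance max column-wise change declaring convergence.
#' @slot selfLoopWeight self-loop weight per node; \code{NA} (default) uses
#'   each node's maximum incident edge weight.
#' @export
setClass("MCLConfig",
         representation(inflation = "numeric", expansion = "integer",
                        pruneThreshold = "numeric", maxIterations = "integer",
                        convergenceTolerance = "numeric",
                        selfLoopWeight = "numeric"))

setValidity("MCLConfig", function(object) {
  msgs <- character()
  if (object@inflation <= 1) msgs <- c(msgs, "inflation must be > 1")
  if (object@expansion < 2L) msgs <- c(msgs, "expansion must be >= 2")
  if (object@pruneThreshold < 0) msgs <- c(msgs, "pruneThreshold must be >= 0")
  if (object@maxIterations < 1L) msgs <- c(msgs, "maxIterations must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' GeneClustering: a partition of network genes into clusters
#'
#' @slot clusters list of character vectors; every clustered gene appears in
#'   exactly one cluster and no cluster is empty.
#' @slot converged FALSE when the clustering was read off a non-converged
#'   MCL iterate.
#' @export
setClass("GeneClustering",
         representation(clusters = "list", converged = "logical"))

setValidity("GeneClustering", function(object) {
  msgs <- character()
  sizes <- lengths(object@clusters)
  if (length(sizes) && any(sizes == 0L)) msgs <- c(msgs, "empty cluster")
  members <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(members)) msgs <- c(msgs, "clusters must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' RankedSignature: the final ordered gene list
#'
#' @slot table data.frame with columns \code{rank}, \code{gene},
#'   \code{cluster}, \code{importance}, \code{regulation} (\code{"up"} or
#'   \code{"down"} in dysregulated samples).
#' @export
setClass("RankedSignature", representation(table = "data.frame"))

setValidity("RankedSignature", function(object) {
  t <- object@table
  msgs <- character()
  need <- c("rank", "gene", "cluster", "importance", "regulation")
  if (!all(need %in% colnames(t)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  if (nrow(t)) {
    if (!identical(sort(t$rank), seq_len(nrow(t)))) msgs <- c(msgs, "ranks must be 1..N unique")
    if (anyDuplicated(t$gene)) msgs <- c(msgs, "genes must be unique")
    if (!all(t$regulation %in% c("up", "down"))) msgs <- c(msgs, "regulation must be up/down")
  }
  if (length(msgs)) msgs else TRUE
})

#' DoseResponseExperiment: dose-annotated expression for one treatment group
#'
#' @slot groupId treatment group identifier (chemical x duration).
#' @slot values gene-by-sample expression matrix.
#' @slot doses nonnegative dose per sample; dose 0 is the control.
#' @export
setClass("DoseResponseExperiment",
         representation(groupId = "character", values = "matrix",
                        doses = "numeric"))

setValidity("DoseResponseExperiment", function(object) {
  msgs <- character()
  if (length(object@doses) != ncol(object@values))
    msgs <- c(msgs, "one dose per sample required")
  if (any(object@doses < 0)) msgs <- c(msgs, "doses must be nonnegative")
  if (!any(object@doses == 0)) msgs <- c(msgs, "a dose-0 control is required")
  if (length(unique(object@doses)) < 4L)
    msgs <- c(msgs, "at least 4 dose levels (incl. control) are required")
  if (min(table(object@doses)) < 2L)
    msgs <- c(msgs, "at least 2 replicates per dose are required")
  if (length(msgs)) msgs else TRUE
})

#' BMDResult: gene- and group-level benchmark doses
#'
#' @slot geneTable per-gene winning model, AIC and BMD (NA with a reason code
#'   when undefined).
#' @slot groupTable per-treatment-group BMD_t with the contributing pathway.
#' @export
setClass("BMDResult",
         representation(geneTable = "data.frame", groupTable = "data.frame"))

#' SimulationConfig: parameters of the synthetic-data generator
#'
#' Encodes the planted structure the generator emulates: correlated gene
#' modules shared across three datasets, labels driven by the informative
#' modules, MCAR missingness, pathway annotation biased toward informative
#' genes, and Hill-shaped dose-response curves with known benchmark doses.
#'
#' @slot nGenes total gene count.
#' @slot nSamples integer vector of per-dataset sample counts (3 datasets).
#' @slot moduleSizes sizes of the planted co-expression modules.
#' @slot withinModuleCorrelation target pairwise correlation within a module.
#' @slot nInformativeModules leading modules whose genes carry the label
#'   effect.
#' @slot labelEffectSize standardized mean shift of informative genes in
#'   dysregulated samples.
#' @slot dysregulatedFraction expected fraction of dysregulated samples.
#' @slot missingRate MCAR missing-entry rate.
#' @slot nPathways number of synthetic gene sets.
#' @slot pathwayEnrichmentBias odds multiplier for annotating an informative
#'   gene (1 = no bias).
#' @slot doseLevels dose levels (incl. 0) of the dose-response design.
#' @slot nReplicates replicates per dose level.
#' @slot trueBmd named numeric: planted benchmark dose per responding gene.
#' @slot doseNoiseSd Gaussian noise sd on the dose-response scale.
#' @slot seed master seed.
#' @export
setClass("SimulationConfig",
         representation(nGenes = "integer", nSamples = "integer",
                        moduleSizes = "integer",
                        withinModuleCorrelation = "numeric",
                        nInformativeModules = "integer",
                        labelEffectSize = "numeric",
                        dysregulatedFraction = "numeric",
                        missingRate = "numeric", nPathways = "integer",
                        pathwayEnrichmentBias = "numeric",
                        doseLevels = "numeric", nReplicates = "integer",
                        trueBmd = "numeric", doseNoiseSd = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (sum(object@moduleSizes) > object@nGenes)
    msgs <- c(msgs, "sum of moduleSizes must not exceed nGenes")
  if (object@withinModuleCorrelation <= 0 || object@withinModuleCorrelation >= 1)
    msgs <- c(msgs, "withinModuleCorrelation must lie in (0, 1)")
  if (object@missingRate < 0 || object@missingRate > 1)
    msgs <- c(msgs, "missingRate must lie in [0, 1]")
  if (object@nInformativeModules > length(object@moduleSizes))
    msgs <- c(msgs, "nInformativeModules exceeds module count")
  if (object@pathwayEnrichmentBias < 1)
    msgs <- c(msgs, "pathwayEnrichmentBias must be >= 1")
  if (object@dysregulatedFraction <= 0 || object@dysregulatedFraction >= 1)
    msgs <- c(msgs, "dysregulatedFraction must lie in (0, 1)")
  if (length(object@nSamples) != 3L)
    msgs <- c(msgs, "nSamples must give counts for 3 datasets")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticBundle: a full synthetic study with ground truth
#'
#' @slot datasets list of three \linkS4class{ExpressionDataset}s.
#' @slot labels list of named label vectors parallel to \code{datasets}.
#' @slot geneSets \linkS4class{GeneSetCollection}.
#' @slot interactions \linkS4class{InteractionGraph}.
#' @slot doseResponse list of \linkS4class{DoseResponseExperiment}s.
#' @slot truth list: \code{moduleAssignment} (gene -> module index, 0 =
#'   background), \code{informativeGenes}, \code{trueBmd} tables per group.
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @export
setClass("SyntheticBundle",
         representation(datasets = "list", labels = "list",
                        geneSets = "GeneSetCollection",
                        interactions = "InteractionGraph",
                        doseResponse = "list", truth = "list",
                        config = "SimulationConfig"))
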