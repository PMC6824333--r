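#' Create a SimulationConfig
#'
#' Defaults describe a desk-scale study shaped like a multi-dataset
#' toxicogenomic training resource: three datasets (human in vitro, rat in
#' vitro, rat in vivo) sharing planted co-expression modules, ~10% missing
#' entries, labels driven by the informative modules, pathway annotation
#' biased toward informative genes, and Hill-shaped dose-response curves
#' with known benchmark doses.
#'
#' @param nGenes,nSamples,moduleSizes,withinModuleCorrelation
#'   module-structure parameters (see \linkS4class{SimulationConfig}).
#' @param nInformativeModules,labelEffectSize,dysregulatedFraction
#'   label-generation parameters.
#' @param missingRate MCAR missing-entry rate (default 0.10).
#' @param nPathways,pathwayEnrichmentBias prior-annotation parameters.
#' @param doseLevels,nReplicates,trueBmd,doseNoiseSd dose-response design;
#'   \code{trueBmd = NULL} plants a default log-spaced table (see
#'   \code{\link{defaultTrueBmd}}).
#' @param seed master seed; all generation is reproducible from it.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nGenes = 600L, nSamples = c(120L, 120L, 120L),
                             moduleSizes = rep(30L, 10L),
                             withinModuleCorrelation = 0.7,
                             nInformativeModules = 3L,
                             labelEffectSize = 1.0,
                             dysregulatedFraction = 0.4,
                             missingRate = 0.10, nPathways = 40L,
                             pathwayEnrichmentBias = 5,
                             doseLevels = c(0, 0.5, 1, 2, 4, 8),
                             nReplicates = 3L, trueBmd = numeric(0),
                             doseNoiseSd = 0.2, seed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      nSamples = as.integer(nSamples),
      moduleSizes = as.integer(moduleSizes),
      withinModuleCorrelation = withinModuleCorrelation,
      nInformativeModules = as.integer(nInformativeModules),
      labelEffectSize = labelEffectSize,
      dysregulatedFraction = dysregulatedFraction,
      missingRate = missingRate, nPathways = as.integer(nPathways),
      pathwayEnrichmentBias = pathwayEnrichmentBias,
      doseLevels = doseLevels, nReplicates = as.integer(nReplicates),
      trueBmd = trueBmd, doseNoiseSd = doseNoiseSd, seed = as.integer(seed))
}

# Canonical (uppercase) gene universe and planted module assignment.
simGenes <- function(config) {
  sprintf("GENE%04d", seq_len(config@nGenes))
}

#' Planted module assignment of a SimulationConfig
#' @param config a \linkS4class{SimulationConfig}.
#' @return named integer vector, gene -> module index (0 = background).
#' @export
moduleAssignment <- function(config) {
  m <- integer(config@nGenes)
  m[seq_len(sum(config@moduleSizes))] <-
    rep(seq_along(config@moduleSizes), config@moduleSizes)
  setNames(m, simGenes(config))
}

#' Informative genes of a SimulationConfig
#' @param config a \linkS4class{SimulationConfig}.
#' @return character vector: genes of the informative modules.
#' @export
informativeGenes <- function(config) {
  m <- moduleAssignment(config)
  names(m)[m >= 1L & m <= config@nInformativeModules]
}

#' Default planted benchmark-dose table
#'
#' When the config carries no explicit \code{trueBmd} table, the first 40
#' genes (or fewer for tiny configs) respond with benchmark doses log-spaced
#' across the middle of the dose range.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return named numeric vector gene -> BMD.
#' @export
defaultTrueBmd <- function(config) {
  if (length(config@trueBmd)) return(config@trueBmd)
  n <- min(40L, config@nGenes)
  pos <- config@doseLevels[config@doseLevels > 0]
  lo <- min(pos) * 0.6
  hi <- max(pos) * 0.375
  setNames(exp(seq(log(lo), log(hi), length.out = n)),
           simGenes(config)[seq_len(n)])
}

#' Generate three ExpressionDatasets with planted modules and labels
#'
#' Genes of a module share a single latent factor per sample, giving
#' expected pairwise correlation \code{withinModuleCorrelation}; background
#' genes are independent.  Each sample is dysregulated with probability
#' \code{dysregulatedFraction}, and informative-module genes are shifted by
#' \code{labelEffectSize} standard deviations in dysregulated samples.
#' Entries go missing uniformly at \code{missingRate}.  Dataset annotations
#' carry an LDH activity (datasets 1--2, in vitro) or a histopathology grade
#' (dataset 3, in vivo) consistent with the planted label, so
#' \code{\link{labelSamples}} reproduces the truth.  Rat datasets use
#' title-case symbol spellings to exercise ortholog harmonization.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{datasets} (list of 3
#'   \linkS4class{ExpressionDataset}s) and \code{labels} (list of named
#'   label vectors).
#' @export
generateExpressionTriplet <- function(config) {
  validObject(config)
  genes <- simGenes(config)
  modules <- moduleAssignment(config)
  info <- informativeGenes(config)
  rho <- config@withinModuleCorrelation
  meta <- list(
    list(id = "human_invitro", species = "human", organ = "liver",
         duration = "24h", case = "upper", endpoint = "ldh"),
    list(id = "rat_invitro", species = "rat", organ = "liver",
         duration = "24h", case = "title", endpoint = "ldh"),
    list(id = "rat_invivo", species = "rat", organ = "liver",
         duration = "28d", case = "title", endpoint = "histopathology"))
  datasets <- vector("list", 3L)
  labels <- vector("list", 3L)
  for (d in 1:3) {
    set.seed(stageSeed(config@seed, paste0("expr", d)))
    n <- config@nSamples[d]
    sampleIds <- sprintf("%s_S%03d", meta[[d]]$id, seq_len(n))
    lab <- ifelse(stats::rbinom(n, 1L, config@dysregulatedFraction) == 1L,
                  "dysregulated", "non_dysregulated")
    factors <- matrix(stats::rnorm(length(config@moduleSizes) * n),
                      nrow = length(config@moduleSizes))
    x <- matrix(stats::rnorm(config@nGenes * n), nrow = config@nGenes,
                dimnames = list(genes, sampleIds))
    inMod <- modules >= 1L
    x[inMod, ] <- sqrt(rho) * factors[modules[inMod], , drop = FALSE] +
      sqrt(1 - rho) * x[inMod, , drop = FALSE]
    x[info, lab == "dysregulated"] <-
      x[info, lab == "dysregulated", drop = FALSE] + config@labelEffectSize
    x <- x + stats::rnorm(config@nGenes, mean = 8, sd = 0.5)  # gene baselines
    if (config@missingRate > 0) {
      miss <- stats::runif(length(x)) < config@missingRate
      x[miss] <- NA_real_
    }
    dys <- lab == "dysregulated"
    if (meta[[d]]$endpoint == "ldh") {
      # inside [95, 105] for non-dysregulated; outside (either tail) otherwise
      ldh <- ifelse(dys,
                    ifelse(stats::runif(n) < 0.5,
                           95 - stats::runif(n, 1, 30),
                           105 + stats::runif(n, 1, 60)),
                    stats::runif(n, 95, 105))
      ann <- data.frame(sample_id = sampleIds, chemical = "simchem",
                        dose = stats::runif(n, 0, 10),
                        duration = meta[[d]]$duration,
                        organ = meta[[d]]$organ, species = meta[[d]]$species,
                        ldh_percent = ldh,
                        histopathology_grade = NA_character_)
    } else {
      grade <- ifelse(dys, sample(c("moderate", "severe"), n, replace = TRUE),
                      sample(c("present", "minimal", "slight"), n, replace = TRUE))
      ann <- data.frame(sample_id = sampleIds, chemical = "simchem",
                        dose = stats::runif(n, 0, 10),
                        duration = meta[[d]]$duration,
                        organ = meta[[d]]$organ, species = meta[[d]]$species,
                        ldh_percent = NA_real_,
                        histopathology_grade = grade)
    }
    rownames(ann) <- sampleIds
    if (meta[[d]]$case == "title")
      rownames(x) <- paste0(substr(genes, 1, 1),
                            tolower(substring(genes, 2)))
    datasets[[d]] <- ExpressionDataset(x, ann, meta[[d]]$id)
    labels[[d]] <- setNames(lab, sampleIds)
  }
  names(datasets) <- names(labels) <- vapply(meta, `[[`, "", "id")
  list(datasets = datasets, labels = labels)
}

#' Generate synthetic prior-knowledge annotations
#'
#' Pathway membership is sampled at a background rate, with the odds of
#' annotating an informative gene multiplied by
#' \code{pathwayEnrichmentBias}.  The interaction graph contains chemical,
#' gene and disease nodes; gene degree is similarly biased toward
#' informative genes.  A minority of edges carry a non-mechanistic
#' association class to exercise the class filter.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param baseRate background pathway-membership probability.
#' @return list with \code{geneSets} (\linkS4class{GeneSetCollection}) and
#'   \code{interactions} (\linkS4class{InteractionGraph}).
#' @export
generatePriorAnnotations <- function(config, baseRate = 0.05) {
  validObject(config)
  genes <- simGenes(config)
  info <- genes %in% informativeGenes(config)
  bias <- config@pathwayEnrichmentBias
  odds <- baseRate / (1 - baseRate)
  pInfo <- (odds * bias) / (1 + odds * bias)
  p <- ifelse(info, pInfo, baseRate)

  set.seed(stageSeed(config@seed, "genesets"))
  nSets <- config@nPathways
  sets <- list()
  family <- character(0)
  if (nSets > 0L) {
    nHallmark <- max(1L, round(nSets * 0.2))
    family <- c(rep("hallmark", nHallmark), rep("kegg", nSets - nHallmark))
    sets <- lapply(seq_len(nSets), function(i) {
      genes[stats::runif(length(genes)) < p]
    })
    names(sets) <- ifelse(family == "hallmark",
                          sprintf("HALLMARK_SIM_%02d", seq_len(nSets)),
                          sprintf("KEGG_SIM_%02d", seq_len(nSets)))
  }
  collection <- new("GeneSetCollection", sets = sets, family = family)

  set.seed(stageSeed(config@seed, "interactions"))
  chemicals <- sprintf("CHEM%02d", 1:15)
  diseases <- sprintf("DIS%02d", 1:10)
  lambda <- ifelse(info, 0.6 * bias, 0.6)
  nEdges <- stats::rpois(length(genes), lambda)
  src <- rep(genes, nEdges)
  partners <- sample(c(chemicals, diseases), length(src), replace = TRUE)
  cls <- sample(c("mechanistic/marker", "therapeutic"), length(src),
                replace = TRUE, prob = c(0.85, 0.15))
  edges <- unique(data.frame(node_a = src, node_b = partners,
                             association_class = cls))
  # a few chemical-disease links for realism
  cd <- data.frame(node_a = sample(chemicals, 10, replace = TRUE),
                   node_b = sample(diseases, 10, replace = TRUE),
                   association_class = "mechanistic/marker")
  edges <- unique(rbind(edges, cd))
  nodes <- rbind(data.frame(id = genes, type = "gene"),
                 data.frame(id = chemicals, type = "chemical"),
                 data.frame(id = diseases, type = "disease"))
  graph <- new("InteractionGraph", nodes = nodes, edges = edges)
  list(geneSets = collection, interactions = graph)
}

#' Generate a dose-response experiment with planted benchmark doses
#'
#' Responding genes follow a Hill curve
#' \eqn{f(d) = a + b d^h / (k^h + d^h)} with \eqn{|b| = 0.3 |a|} and
#' \eqn{k} chosen so the dose producing a 10% change relative to control
#' equals the planted benchmark dose; non-responders are flat.  Gaussian
#' noise of sd \code{doseNoiseSd} is added throughout.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param groupId treatment-group identifier.
#' @param trueBmd named numeric gene -> BMD; defaults to
#'   \code{\link{defaultTrueBmd}(config)}.
#' @param seed seed for this group (defaults to a fan-out of the config
#'   seed and \code{groupId}).
#' @return a \linkS4class{DoseResponseExperiment}.
#' @export
generateDoseResponse <- function(config, groupId = "group1", trueBmd = NULL,
                                 seed = NULL) {
  validObject(config)
  if (!any(config@doseLevels == 0) || length(unique(config@doseLevels)) < 4L)
    toxsigValidationError("doseLevels must contain 0 and >= 4 distinct levels")
  if (config@nReplicates < 2L)
    toxsigValidationError("at least 2 replicates per dose are required")
  trueBmd <- trueBmd %||% defaultTrueBmd(config)
  genes <- simGenes(config)
  if (!all(names(trueBmd) %in% genes))
    toxsigValidationError("trueBmd references unknown genes")
  if (any(trueBmd <= 0))
    toxsigValidationError("planted BMDs must be positive")
  if (any(trueBmd > max(config@doseLevels)))
    warning("some planted BMDs fall outside the tested dose range")
  set.seed(seed %||% stageSeed(config@seed, paste0("dose_", groupId)))
  doses <- rep(sort(config@doseLevels), each = config@nReplicates)
  sampleIds <- sprintf("%s_S%02d", groupId, seq_along(doses))
  hillN <- 2
  a <- stats::rnorm(length(genes), 8, 0.5)
  dir <- sample(c(-1, 1), length(genes), replace = TRUE)
  x <- matrix(rep(a, length(doses)), nrow = length(genes),
              dimnames = list(genes, sampleIds))
  for (g in names(trueBmd)) {
    i <- match(g, genes)
    b <- dir[i] * 0.3 * abs(a[i])
    k <- trueBmd[[g]] * 2^(1 / hillN)  # 10% of |a| reached at d = trueBmd
    x[i, ] <- a[i] + b * doses^hillN / (k^hillN + doses^hillN)
  }
  x <- x + stats::rnorm(length(x), sd = config@doseNoiseSd)
  new("DoseResponseExperiment", groupId = groupId, values = x, doses = doses)
}

#' Generate a complete synthetic study bundle
#'
#' Assembles the expression triplet with labels, prior-knowledge
#' annotations, and \code{nGroups} dose-response treatment groups whose
#' planted benchmark doses are the default table scaled per group
#' (log-spaced factors in [0.5, 2]); each group also gets a planted apical
#' benchmark dose \code{BMD_a} proportional to its scale with
#' \code{bmdaNoiseFold}-fold lognormal noise.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nGroups number of dose-response treatment groups.
#' @param bmdaNoiseFold maximal fold-error of the planted apical BMD.
#' @return a \linkS4class{SyntheticBundle}.
#' @export
generateSyntheticBundle <- function(config = simulationConfig(), nGroups = 6L,
                                    bmdaNoiseFold = 3) {
  validObject(config)
  triplet <- generateExpressionTriplet(config)
  prior <- generatePriorAnnotations(config)
  base <- defaultTrueBmd(config)
  scales <- if (nGroups > 1L)
    exp(seq(log(0.5), log(2), length.out = nGroups)) else 1
  set.seed(stageSeed(config@seed, "bmda"))
  noise <- exp(stats::runif(nGroups, -log(bmdaNoiseFold), log(bmdaNoiseFold)))
  groups <- vector("list", nGroups)
  trueTables <- vector("list", nGroups)
  bmda <- numeric(nGroups)
  for (g in seq_len(nGroups)) {
    id <- sprintf("group%d", g)
    trueTables[[g]] <- base * scales[g]
    groups[[g]] <- generateDoseResponse(config, id, trueTables[[g]])
    bmda[g] <- stats::median(trueTables[[g]]) * noise[g]
  }
  names(groups) <- names(trueTables) <- sprintf("group%d", seq_len(nGroups))
  new("SyntheticBundle",
      datasets = triplet$datasets, labels = triplet$labels,
      geneSets = prior$geneSets, interactions = prior$interactions,
      doseResponse = groups,
      truth = list(moduleAssignment = moduleAssignment(config),
                   informativeGenes = informativeGenes(config),
                   trueBmd = trueTables,
                   groupBmda = setNames(bmda, names(groups))),
      config = config)
}

#' Write a SyntheticBundle's fixture files
#'
#' Writes expression/annotation/label TSVs per dataset, the gene sets as
#' GMT, the interaction edge list as TSV, dose tables and expression per
#' treatment group, and the ground truth as JSON.
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeSyntheticBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle@datasets)) {
    d <- bundle@datasets[[nm]]
    writeExpressionTsv(d, file.path(dir, paste0(nm, "_expression.tsv")))
    utils::write.table(sampleAnnotations(d),
                       file.path(dir, paste0(nm, "_annotations.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLabelsTsv(bundle@labels[[nm]], file.path(dir, paste0(nm, "_labels.tsv")))
  }
  writeGmt(bundle@geneSets, file.path(dir, "gene_sets.gmt"))
  writeInteractionTsv(bundle@interactions, file.path(dir, "interactions.tsv"))
  for (nm in names(bundle@doseResponse)) {
    e <- bundle@doseResponse[[nm]]
    utils::write.table(data.frame(gene = rownames(e@values), e@values,
                                  check.names = FALSE),
                       file.path(dir, paste0(nm, "_doseresponse.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = colnames(e@values),
                                  treatment_group = nm, dose = e@doses),
                       file.path(dir, paste0(nm, "_doses.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- bundle@truth
  truth$moduleAssignment <- as.list(truth$moduleAssignment)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
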