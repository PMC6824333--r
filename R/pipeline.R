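#' Assemble a pipeline run configuration
#'
#' @param outDir artifact directory (created if needed).
#' @param seed global seed; stage seeds are fanned out deterministically.
#' @param correlationThreshold co-expression edge cutoff (default 0.6).
#' @param reweightMode \code{"mean"} or \code{"product"} (see
#'   \code{\link{reweightEdges}}).
#' @param mcl an \linkS4class{MCLConfig}.
#' @param signatureSizes requested signature sizes; smaller sizes are
#'   top-k prefixes of the ranking computed at the largest size (reference
#'   presets: 384, 1000, 1500).
#' @param classifiers evaluation panel (default
#'   \code{\link{DEFAULT_CLASSIFIERS}}).
#' @param nFolds CV folds.
#' @param baselineRepeats random-baseline repeats (0 disables the
#'   baseline stage; 500 at reference scale).
#' @param bmdFdrCutoff,bmr BMD-stage thresholds.
#' @param simulation a \linkS4class{SimulationConfig} used when no bundle
#'   is supplied.
#' @param stages subset of \code{c("simulate", "network", "prior",
#'   "cluster", "select", "evaluate", "bmd")} or \code{"all"}.
#' @return a named list (the run configuration).
#' @export
runConfig <- function(outDir = tempfile("toxsig_run_"), seed = 1L,
                      correlationThreshold = 0.6, reweightMode = "mean",
                      mcl = mclConfig(), signatureSizes = 1000L,
                      classifiers = DEFAULT_CLASSIFIERS, nFolds = 5L,
                      baselineRepeats = 0L, bmdFdrCutoff = 0.05, bmr = 0.10,
                      simulation = simulationConfig(), stages = "all") {
  if (any(signatureSizes < 1L))
    toxsigValidationError("signature sizes must be >= 1")
  if (correlationThreshold < 0 || correlationThreshold > 1)
    toxsigValidationError("correlationThreshold must lie in [0, 1]")
  list(outDir = outDir, seed = as.integer(seed),
       correlationThreshold = correlationThreshold,
       reweightMode = reweightMode, mcl = mcl,
       signatureSizes = sort(as.integer(signatureSizes)),
       classifiers = classifiers, nFolds = as.integer(nFolds),
       baselineRepeats = as.integer(baselineRepeats),
       bmdFdrCutoff = bmdFdrCutoff, bmr = bmr,
       simulation = simulation, stages = stages)
}

stageEnabled <- function(config, stage) {
  identical(config$stages, "all") || stage %in% config$stages
}

runStage <- function(name, expr, log = TRUE) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    if (inherits(e, "toxsig_error")) stop(e)
    toxsigStageError(name, "%s", conditionMessage(e))
  })
  if (log)
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the gene-prioritization pipeline end to end
#'
#' Executes data preparation, co-expression networking, prior-knowledge
#' scoring, network re-weighting and clustering, signature selection, and
#' the optional evaluation and benchmark-dose stages, writing every
#' intermediate artifact plus a manifest with content checksums.  A fixed
#' config + seed reproduces a checksum-identical manifest.
#'
#' @param config a \code{\link{runConfig}} list.
#' @param bundle optional \linkS4class{SyntheticBundle}; when NULL one is
#'   generated from \code{config$simulation} (its seed overridden by
#'   \code{config$seed}).
#' @return invisible list of in-memory artifacts (bundle, networks,
#'   priors, clustering, signatures, evaluation, bmd, manifest path).
#' @export
runPipeline <- function(config = runConfig(), bundle = NULL) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  art <- list()

  if (is.null(bundle)) {
    bundle <- runStage("simulate", {
      sim <- config$simulation
      sim@seed <- stageSeed(config$seed, "simulate")
      generateSyntheticBundle(sim)
    })
  }
  art$bundle <- bundle
  if (stageEnabled(config, "simulate"))
    runStage("write_fixtures",
             writeSyntheticBundle(bundle, file.path(config$outDir, "fixtures")),
             log = FALSE)

  prepared <- runStage("prepare", {
    harmonizeOrthologs(lapply(bundle@datasets, mergeDuplicateGenes))
  })
  labels <- bundle@labels

  if (stageEnabled(config, "network")) {
    art$networks <- runStage("network", {
      nets <- lapply(prepared, correlationNetwork,
                     threshold = config$correlationThreshold)
      consensus <- consensusNetwork(nets)
      for (i in seq_along(nets))
        writeEdgeTsv(nets[[i]], file.path(config$outDir,
                                          sprintf("network_%s.tsv", names(prepared)[i])))
      writeEdgeTsv(consensus, file.path(config$outDir, "network_consensus.tsv"))
      list(perDataset = nets, consensus = consensus)
    })
  }

  if (stageEnabled(config, "prior")) {
    art$priors <- runStage("prior", {
      universe <- rownames(prepared[[1L]])
      features <- encodePriorFeatures(bundle@geneSets, bundle@interactions,
                                      universe)
      priors <- computePriorScores(features,
                                   seed = stageSeed(config$seed, "prior"))
      writePriorTsv(priors, file.path(config$outDir, "prior_scores.tsv"))
      priors
    })
  }

  if (stageEnabled(config, "cluster")) {
    clusterOut <- runStage("cluster", {
      reweighted <- reweightEdges(art$networks$consensus, art$priors,
                                  mode = config$reweightMode)
      writeEdgeTsv(reweighted, file.path(config$outDir, "network_reweighted.tsv"))
      cl <- mclCluster(reweighted, config$mcl)
      writeClusters(cl, file.path(config$outDir, "clusters.txt"))
      list(reweighted = reweighted, clustering = cl)
    })
    art$reweighted <- clusterOut$reweighted
    art$clustering <- clusterOut$clustering
  }

  if (stageEnabled(config, "select")) {
    art$signatures <- runStage("select", {
      maxSize <- max(config$signatureSizes)
      primary <- prepared[[1L]]
      full <- selectSignature(primary, labels[[1L]], art$clustering,
                              size = maxSize, nFolds = config$nFolds,
                              seed = stageSeed(config$seed, "select"))
      sigs <- lapply(config$signatureSizes, function(s) {
        tab <- utils::head(signatureTable(full), s)
        sig <- new("RankedSignature", table = tab)
        writeSignatureTsv(sig, file.path(config$outDir,
                                         sprintf("signature_%d.tsv", s)))
        sig
      })
      names(sigs) <- as.character(config$signatureSizes)
      sigs
    })
  }

  if (stageEnabled(config, "evaluate")) {
    art$evaluation <- runStage("evaluate", {
      evalDataset <- prepared[[length(prepared)]]
      evalLabels <- labels[[length(labels)]]
      reports <- lapply(names(art$signatures), function(s) {
        genes <- signatureGenes(art$signatures[[s]])
        crossValidateGeneSet(evalDataset, evalLabels, genes,
                             classifiers = config$classifiers,
                             nFolds = config$nFolds,
                             seed = stageSeed(config$seed, "evaluate"),
                             geneSetId = sprintf("signature_%s", s))
      })
      names(reports) <- names(art$signatures)
      for (s in names(reports))
        writeEvaluationReport(reports[[s]],
                              file.path(config$outDir,
                                        sprintf("evaluation_%s.json", s)),
                              csvPath = file.path(config$outDir,
                                                  sprintf("evaluation_%s.csv", s)))
      out <- list(reports = reports)
      if (config$baselineRepeats > 0L) {
        maxSize <- max(config$signatureSizes)
        out$baseline <- randomBaseline(evalDataset, evalLabels,
                                       setSize = maxSize,
                                       nRepeats = config$baselineRepeats,
                                       classifiers = config$classifiers,
                                       nFolds = config$nFolds,
                                       seed = stageSeed(config$seed, "baseline"))
        out$vsRandom <- compareToRandom(reports[[as.character(maxSize)]],
                                        out$baseline)
        utils::write.table(out$vsRandom,
                           file.path(config$outDir, "vs_random.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      out
    })
  }

  if (stageEnabled(config, "bmd") && length(bundle@doseResponse)) {
    art$bmd <- runStage("bmd", {
      res <- bmdAnalysis(bundle@doseResponse, bundle@geneSets,
                         fdrCutoff = config$bmdFdrCutoff,
                         bmrRelative = config$bmr)
      utils::write.table(res@geneTable,
                         file.path(config$outDir, "bmd_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res@groupTable,
                         file.path(config$outDir, "bmd_groups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out <- list(result = res)
      if (!is.null(bundle@truth$groupBmda)) {
        bmdts <- setNames(res@groupTable$bmdt, res@groupTable$group)
        out$concordance <- concordance(bmdts, bundle@truth$groupBmda)
      }
      out
    })
  }

  manifestPath <- file.path(config$outDir, "manifest.json")
  files <- sort(setdiff(list.files(config$outDir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = config$seed,
    config = list(correlationThreshold = config$correlationThreshold,
                  reweightMode = config$reweightMode,
                  inflation = config$mcl@inflation,
                  signatureSizes = config$signatureSizes,
                  classifiers = config$classifiers,
                  nFolds = config$nFolds,
                  baselineRepeats = config$baselineRepeats,
                  bmdFdrCutoff = config$bmdFdrCutoff, bmr = config$bmr),
    checksums = as.list(tools::md5sum(file.path(config$outDir, files))) |>
      setNames(files))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  art$manifest <- manifestPath
  invisible(art)
}
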