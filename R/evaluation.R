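# Cross-validated evaluation of gene sets with a classifier panel,
# confusion-matrix metrics, random baselines and significance testing.

METRIC_NAMES <- c("sensitivity", "specificity", "precision", "gmean",
                  "f1", "f05")

#' Confusion counts from truth/prediction vectors
#'
#' @param truth,predicted label vectors; \code{positive} is the
#'   "dysregulated" class.
#' @param positive positive-class label.
#' @return list with TP, FP, TN, FN.
#' @export
confusionCounts <- function(truth, predicted, positive = "dysregulated") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  list(TP = sum(predicted == positive & truth == positive),
       FP = sum(predicted == positive & truth != positive),
       TN = sum(predicted != positive & truth != positive),
       FN = sum(predicted != positive & truth == positive))
}

ratio0 <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from confusion counts
#'
#' sensitivity = TP/(TP+FN); specificity = TN/(TN+FP);
#' precision = TP/(TP+FP); GMean = sqrt(sensitivity * specificity);
#' F1 = 2 * precision * sensitivity / (precision + sensitivity);
#' F0.5 = 1.25 * precision * sensitivity / (0.25 * precision + sensitivity).
#' Any 0/0 ratio is defined as 0.
#'
#' @param counts list with TP, FP, TN, FN (see
#'   \code{\link{confusionCounts}}).
#' @return named numeric vector of the six metrics, in [0, 1].
#' @export
computeMetrics <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  sens <- ratio0(counts$TP, counts$TP + counts$FN)
  spec <- ratio0(counts$TN, counts$TN + counts$FP)
  prec <- ratio0(counts$TP, counts$TP + counts$FP)
  metricsFromRates(sens, spec, prec)
}

#' Derived metrics from the three base rates
#'
#' @param sensitivity,specificity,precision base rates in [0, 1].
#' @return named numeric vector of the six metrics.
#' @export
metricsFromRates <- function(sensitivity, specificity, precision) {
  gmean <- sqrt(sensitivity * specificity)
  f1 <- ratio0(2 * precision * sensitivity, precision + sensitivity)
  f05 <- ratio0(1.25 * precision * sensitivity,
                0.25 * precision + sensitivity)
  c(sensitivity = sensitivity, specificity = specificity,
    precision = precision, gmean = gmean, f1 = f1, f05 = f05)
}

## ---- classifier registry ---------------------------------------------------

# Each entry: function(xTrain, yTrain, xTest, seed) -> predicted factor.
# A classifier that cannot be fitted on a fold (e.g. QDA on a singular
# within-class covariance) falls back to the training majority class.
classifierRegistry <- function() {
  majority <- function(y) names(which.max(table(y)))
  safe <- function(fit) function(xTrain, yTrain, xTest, seed) {
    tryCatch(fit(xTrain, yTrain, xTest, seed),
             error = function(e) {
               warning(sprintf("classifier fold failed (%s); predicting majority class",
                               conditionMessage(e)))
               factor(rep(majority(yTrain), nrow(xTest)), levels = levels(yTrain))
             })
  }
  list(
    knn = safe(function(xTr, yTr, xTe, seed) {
      set.seed(seed)
      class::knn(xTr, xTe, yTr, k = 3L)
    }),
    dt = safe(function(xTr, yTr, xTe, seed) {
      d <- data.frame(xTr, check.names = FALSE)
      d$.y <- yTr
      fit <- rpart::rpart(.y ~ ., data = d, method = "class")
      predict(fit, data.frame(xTe, check.names = FALSE), type = "class")
    }),
    nbc = safe(function(xTr, yTr, xTe, seed) {
      fit <- e1071::naiveBayes(xTr, yTr)
      predict(fit, xTe)
    }),
    qda = safe(function(xTr, yTr, xTe, seed) {
      fit <- MASS::qda(xTr, grouping = yTr)
      predict(fit, xTe)$class
    }),
    lda = safe(function(xTr, yTr, xTe, seed) {
      fit <- MASS::lda(xTr, grouping = yTr)
      predict(fit, xTe)$class
    }),
    rf = safe(function(xTr, yTr, xTe, seed) {
      set.seed(seed)
      fit <- randomForest::randomForest(xTr, yTr, ntree = 500L)
      predict(fit, xTe)
    }))
}

#' The default classifier panel
#'
#' Five classifiers: LDA, naive Bayes, QDA, decision tree and random
#' forest.  \code{"knn"} (K = 3) is also registered and may be substituted
#' via the \code{classifiers} argument of
#' \code{\link{crossValidateGeneSet}}.
#' @export
DEFAULT_CLASSIFIERS <- c("lda", "nbc", "qda", "dt", "rf")

#' Cross-validate a gene subset with a classifier panel
#'
#' For each classifier, out-of-fold predictions from stratified k-fold CV
#' are pooled into one confusion matrix (or averaged per fold with
#' \code{perFoldAverage = TRUE}) and converted to metrics.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param labels named label vector over the dataset samples.
#' @param genes gene subset (must exist in the dataset).
#' @param classifiers character vector of registry names (default
#'   \code{DEFAULT_CLASSIFIERS}).
#' @param nFolds folds (default 5).
#' @param seed RNG seed (folds + stochastic classifiers).
#' @param perFoldAverage average per-fold metrics instead of pooling
#'   predictions.
#' @param geneSetId identifier recorded in the report.
#' @return an evaluation report: list with \code{geneSetId},
#'   \code{metrics} (classifier x metric matrix), \code{mean}, \code{sd}
#'   (across the classifier panel), \code{classifiers}, \code{seed}.
#' @export
crossValidateGeneSet <- function(dataset, labels, genes,
                                 classifiers = DEFAULT_CLASSIFIERS,
                                 nFolds = 5L, seed = 1L,
                                 perFoldAverage = FALSE,
                                 geneSetId = "gene_set") {
  registry <- classifierRegistry()
  unknown <- setdiff(classifiers, names(registry))
  if (length(unknown))
    toxsigValidationError("unknown classifier(s) %s; registry: %s",
                          paste(unknown, collapse = ", "),
                          paste(names(registry), collapse = ", "))
  missing <- setdiff(genes, rownames(dataset))
  if (length(missing))
    toxsigValidationError("genes absent from dataset: %s",
                          paste(utils::head(missing, 5L), collapse = ", "))
  y <- factor(labels[colnames(dataset)])
  checkTwoClasses(y)
  x <- imputeForModel(t(exprsValues(dataset)[genes, , drop = FALSE]))
  folds <- stratifiedFolds(y, nFolds, seed)
  metrics <- matrix(NA_real_, nrow = length(classifiers),
                    ncol = length(METRIC_NAMES),
                    dimnames = list(classifiers, METRIC_NAMES))
  for (clf in classifiers) {
    predFun <- registry[[clf]]
    if (perFoldAverage) {
      per <- matrix(NA_real_, nrow = nFolds, ncol = length(METRIC_NAMES))
      for (f in seq_len(nFolds)) {
        tr <- folds != f
        pred <- predFun(x[tr, , drop = FALSE], y[tr],
                        x[!tr, , drop = FALSE],
                        stageSeed(seed, paste0(clf, f)))
        per[f, ] <- computeMetrics(confusionCounts(y[!tr], pred))
      }
      metrics[clf, ] <- colMeans(per)
    } else {
      pooled <- factor(rep(NA_character_, length(y)), levels = levels(y))
      for (f in seq_len(nFolds)) {
        tr <- folds != f
        pooled[!tr] <- predFun(x[tr, , drop = FALSE], y[tr],
                               x[!tr, , drop = FALSE],
                               stageSeed(seed, paste0(clf, f)))
      }
      metrics[clf, ] <- computeMetrics(confusionCounts(y, pooled))
    }
  }
  list(geneSetId = geneSetId, metrics = metrics,
       mean = colMeans(metrics), sd = apply(metrics, 2L, stats::sd),
       classifiers = classifiers, seed = seed)
}

#' Random-gene-set baseline
#'
#' Evaluates \code{nRepeats} uniformly sampled gene subsets of size
#' \code{setSize} and summarizes: per-classifier metrics averaged over
#' repeats, and the across-classifier mean and sd of those averages
#' (comparable to a single gene set's report).
#'
#' @param dataset,labels,classifiers,nFolds,seed as in
#'   \code{\link{crossValidateGeneSet}}.
#' @param setSize genes per random subset.
#' @param nRepeats number of random subsets (500 at reference scale).
#' @return list with \code{perClassifier} (classifier x metric averages),
#'   \code{mean}, \code{sd}, \code{repeatMeans} (per-repeat
#'   across-classifier means), \code{classifiers}, \code{nRepeats}.
#' @export
randomBaseline <- function(dataset, labels, setSize, nRepeats = 500L,
                           classifiers = DEFAULT_CLASSIFIERS, nFolds = 5L,
                           seed = 1L) {
  genes <- rownames(dataset)
  if (setSize > length(genes))
    toxsigValidationError("setSize exceeds gene count")
  acc <- array(NA_real_, dim = c(nRepeats, length(classifiers),
                                 length(METRIC_NAMES)),
               dimnames = list(NULL, classifiers, METRIC_NAMES))
  for (r in seq_len(nRepeats)) {
    set.seed(stageSeed(seed, paste0("baseline", r)))
    subset <- sample(genes, setSize)
    rep <- crossValidateGeneSet(dataset, labels, subset,
                                classifiers = classifiers, nFolds = nFolds,
                                seed = stageSeed(seed, paste0("cv", r)),
                                geneSetId = sprintf("random_%d", r))
    acc[r, , ] <- rep$metrics
  }
  perClassifier <- apply(acc, c(2L, 3L), mean)
  list(perClassifier = perClassifier,
       mean = colMeans(perClassifier),
       sd = apply(perClassifier, 2L, stats::sd),
       repeatMeans = apply(acc, c(1L, 3L), mean),
       classifiers = classifiers, nRepeats = nRepeats)
}

#' Compare a gene-set report against the random baseline
#'
#' Per metric, a two-sample Welch t-test between the gene set's
#' per-classifier metric values and the baseline's per-classifier averages
#' (both over the same classifier panel).
#'
#' @param report a \code{\link{crossValidateGeneSet}} report.
#' @param baseline a \code{\link{randomBaseline}} summary.
#' @param alpha significance level (default 0.1).
#' @return data.frame with metric, t statistic, p value and significance
#'   flag.
#' @export
compareToRandom <- function(report, baseline, alpha = 0.1) {
  if (!identical(report$classifiers, baseline$classifiers))
    toxsigValidationError("classifier panels differ: {%s} vs {%s}",
                          paste(report$classifiers, collapse = ", "),
                          paste(baseline$classifiers, collapse = ", "))
  rows <- lapply(METRIC_NAMES, function(m) {
    x <- report$metrics[, m]
    y <- baseline$perClassifier[, m]
    tt <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_))
    data.frame(metric = m, t = unname(tt$statistic),
               p_value = unname(tt$p.value),
               significant = !is.na(tt$p.value) && tt$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' Improvement table between gene-set reports
#'
#' Compares the first report's metrics against each other report:
#' absolute delta \code{m_a - m_b} (same scale as the inputs) and relative
#' delta \code{100 * (m_a - m_b) / m_b} in percent (\code{NA} when the
#' reference metric is 0).
#'
#' @param reports named list of >= 2 reports
#'   (\code{\link{crossValidateGeneSet}} output) or named metric vectors.
#' @return data.frame with columns reference, metric, value_a, value_b,
#'   absolute, relative_pct.
#' @export
compareGeneSets <- function(reports) {
  if (length(reports) < 2L)
    toxsigValidationError("need >= 2 reports to compare")
  vec <- function(r) if (is.list(r) && !is.null(r$mean)) r$mean else r
  a <- vec(reports[[1L]])
  rows <- lapply(seq_along(reports)[-1L], function(i) {
    b <- vec(reports[[i]])
    shared <- intersect(names(a), names(b))
    data.frame(reference = names(reports)[i] %||% paste0("set", i),
               metric = shared,
               value_a = unname(a[shared]), value_b = unname(b[shared]),
               absolute = unname(a[shared] - b[shared]),
               relative_pct = ifelse(b[shared] == 0, NA_real_,
                                     100 * (a[shared] - b[shared]) / b[shared]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an evaluation report as JSON (and optionally a Table-4-style CSV)
#'
#' @param report a \code{\link{crossValidateGeneSet}} report.
#' @param path output JSON path.
#' @param csvPath optional CSV path: one row per classifier plus the
#'   mean/sd summary rows, metrics in percent.
#' @export
writeEvaluationReport <- function(report, path, csvPath = NULL) {
  out <- list(gene_set_id = report$geneSetId,
              classifiers = report$classifiers,
              per_classifier = as.data.frame(report$metrics),
              mean = as.list(report$mean), sd = as.list(report$sd),
              seed = report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csvPath)) {
    m <- rbind(report$metrics, mean = report$mean, sd = report$sd) * 100
    utils::write.table(data.frame(model = rownames(m), round(m, 2)),
                       csvPath, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
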