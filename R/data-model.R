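#' Construct an ExpressionDataset
#'
#' @param values numeric gene-by-sample matrix of log-scale intensities;
#'   \code{NA} entries mark missing values.  Row names are gene symbols,
#'   column names sample ids.
#' @param annotations optional data.frame of per-sample annotations (rows
#'   matched to columns of \code{values} by sample id or position); expected
#'   columns \code{chemical}, \code{dose}, \code{duration}, \code{organ},
#'   \code{species} and optionally \code{ldh_percent} or
#'   \code{histopathology_grade}.
#' @param datasetId identifying string.
#' @return an \linkS4class{ExpressionDataset}.
#' @export
ExpressionDataset <- function(values, annotations = NULL, datasetId = "dataset") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(annotations)) {
    annotations <- S4Vectors::DataFrame(row.names = colnames(values))
  } else {
    annotations <- S4Vectors::DataFrame(annotations)
    if (!is.null(rownames(annotations)) &&
        all(colnames(values) %in% rownames(annotations)))
      annotations <- annotations[colnames(values), , drop = FALSE]
    if (nrow(annotations) != ncol(values))
      toxsigValidationError("annotations (%d rows) do not match samples (%d)",
                            nrow(annotations), ncol(values))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = annotations)
  new("ExpressionDataset", se, datasetId = datasetId)
}

#' The five-level ordinal histopathology severity scale
#' @export
HISTOPATHOLOGY_GRADES <- c("present", "minimal", "slight", "moderate", "severe")

#' Binarize LDH activity into dysregulation labels
#'
#' Lactate dehydrogenase activity (% of control) proxies cellular injury in
#' vitro.  Values strictly above \code{high} or strictly below \code{low}
#' are labelled \code{"dysregulated"}; everything in the closed band
#' \code{[low, high]} (controls and non-toxic exposures) is
#' \code{"non_dysregulated"}.
#'
#' @param ldh_percent numeric vector of LDH activity values (\%), >= 0.
#' @param low,high band limits in percent (defaults 95 and 105).
#' @return character vector of labels.
#' @export
binarizeLdh <- function(ldh_percent, low = 95, high = 105) {
  if (any(is.na(ldh_percent)))
    toxsigValidationError("missing LDH value: cannot label sample(s) %s",
                          paste(which(is.na(ldh_percent)), collapse = ", "))
  if (any(ldh_percent < 0))
    toxsigValidationError("negative LDH value: cannot label sample(s) %s",
                          paste(which(ldh_percent < 0), collapse = ", "))
  ifelse(ldh_percent > high | ldh_percent < low,
         "dysregulated", "non_dysregulated")
}

#' Binarize ordinal histopathology grades into dysregulation labels
#'
#' The first three severity levels (present, minimal, slight) map to
#' \code{"non_dysregulated"}; moderate and severe map to
#' \code{"dysregulated"}.
#'
#' @param grade character vector of grades on the five-level scale.
#' @return character vector of labels.
#' @export
binarizeHistopathology <- function(grade) {
  bad <- !grade %in% HISTOPATHOLOGY_GRADES
  if (any(bad))
    toxsigValidationError("unknown histopathology grade(s): %s",
                          paste(unique(grade[bad]), collapse = ", "))
  ifelse(grade %in% c("moderate", "severe"), "dysregulated", "non_dysregulated")
}

#' Derive binary labels from an ExpressionDataset's annotations
#'
#' Uses \code{ldh_percent} when present, otherwise
#' \code{histopathology_grade}.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @return named character vector (sample id -> label).
#' @export
labelSamples <- function(dataset) {
  ann <- sampleAnnotations(dataset)
  if ("ldh_percent" %in% colnames(ann) && any(!is.na(ann$ldh_percent))) {
    lab <- binarizeLdh(ann$ldh_percent)
  } else if ("histopathology_grade" %in% colnames(ann)) {
    lab <- binarizeHistopathology(ann$histopathology_grade)
  } else {
    toxsigValidationError("dataset '%s' has neither ldh_percent nor histopathology_grade",
                          datasetId(dataset))
  }
  setNames(lab, colnames(dataset))
}

#' Merge duplicate gene rows by per-sample averaging
#'
#' Rows sharing a gene symbol are replaced by their per-sample mean; missing
#' entries are ignored sample by sample (a sample missing in every duplicate
#' stays missing).
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @return an \linkS4class{ExpressionDataset} with unique gene symbols.
#' @export
mergeDuplicateGenes <- function(dataset) {
  v <- exprsValues(dataset)
  if (!anyDuplicated(rownames(v))) return(dataset)
  f <- factor(rownames(v), levels = unique(rownames(v)))
  merged <- rowsum(ifelse(is.na(v), 0, v), f, reorder = FALSE) /
    rowsum((!is.na(v)) * 1, f, reorder = FALSE)
  merged[is.nan(merged)] <- NA_real_
  ExpressionDataset(merged, sampleAnnotations(dataset), datasetId(dataset))
}

#' Restrict datasets to their shared (ortholog-matched) gene universe
#'
#' Gene symbols are matched case-insensitively across datasets (e.g. rat
#' \code{Ddr1} matches human \code{DDR1}); genes without a match in every
#' dataset are dropped.  Output datasets share one gene universe in
#' canonical uppercase spelling, in a common order.
#'
#' @param datasets list of >= 2 \linkS4class{ExpressionDataset}s with unique
#'   gene symbols (run \code{\link{mergeDuplicateGenes}} first if needed).
#' @return list of \linkS4class{ExpressionDataset}s over the shared genes.
#' @export
harmonizeOrthologs <- function(datasets) {
  if (length(datasets) < 2L)
    toxsigValidationError("harmonizeOrthologs needs at least 2 datasets")
  upper <- lapply(datasets, function(d) toupper(rownames(d)))
  for (i in seq_along(upper))
    if (anyDuplicated(upper[[i]]))
      toxsigValidationError(
        "dataset '%s' has case-ambiguous duplicate symbols; merge duplicates first",
        datasetId(datasets[[i]]))
  shared <- Reduce(intersect, upper)
  if (length(shared) == 0L)
    toxsigValidationError("no shared genes across the %d datasets", length(datasets))
  shared <- sort(shared)
  lapply(datasets, function(d) {
    v <- exprsValues(d)
    rownames(v) <- toupper(rownames(v))
    ExpressionDataset(v[shared, , drop = FALSE], sampleAnnotations(d),
                      datasetId(d))
  })
}

## ---- plain-text interfaces -------------------------------------------------

#' Read an expression TSV (first column gene symbol, header of sample ids,
#' empty cells = missing)
#' @param path file path.
#' @param datasetId dataset identifier.
#' @param annotations optional annotation data.frame (see
#'   \code{\link{ExpressionDataset}}).
#' @return an \linkS4class{ExpressionDataset}.
#' @export
readExpressionTsv <- function(path, datasetId = basename(path), annotations = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  ExpressionDataset(m, annotations, datasetId)
}

#' Write an expression TSV
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param path output path.
#' @export
writeExpressionTsv <- function(dataset, path) {
  v <- exprsValues(dataset)
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a sample-annotation TSV (columns sample_id, chemical, dose, duration,
#' organ, species, ldh_percent, histopathology_grade)
#' @param path file path.
#' @return data.frame with sample ids as row names.
#' @export
readAnnotationTsv <- function(path) {
  a <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  rownames(a) <- a$sample_id
  a
}

#' Read / write a labels TSV (columns sample_id, label)
#' @param path file path.
#' @return named character vector of labels.
#' @export
readLabelsTsv <- function(path) {
  d <- utils::read.delim(path)
  setNames(as.character(d$label), d$sample_id)
}

#' @rdname readLabelsTsv
#' @param labels named character vector.
#' @export
writeLabelsTsv <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels), label = labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
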