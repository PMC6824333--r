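# Transcriptomic benchmark-dose pipeline: ANOVA prefilter, multi-model
# least-squares fits, AIC model selection, gene-level BMD at a 10% relative
# benchmark response, pathway-level aggregation, and concordance with
# apical benchmark doses.

#' One-way ANOVA prefilter of dose-responsive genes
#'
#' Classic one-way ANOVA of expression across dose groups per gene,
#' Benjamini-Hochberg adjusted; genes with adjusted p <= cutoff pass.
#'
#' @param experiment a \linkS4class{DoseResponseExperiment}.
#' @param fdrCutoff BH-adjusted p-value cutoff (default 0.05).
#' @return character vector of passing genes.
#' @export
anovaPrefilter <- function(experiment, fdrCutoff = 0.05) {
  doses <- factor(experiment@doses)
  if (nlevels(doses) < 2L)
    toxsigValidationError("ANOVA needs >= 2 dose groups")
  p <- apply(experiment@values, 1L, function(y) {
    stats::oneway.test(y ~ doses, var.equal = TRUE)$p.value
  })
  padj <- stats::p.adjust(p, method = "BH")
  rownames(experiment@values)[!is.na(padj) & padj <= fdrCutoff]
}

# ---- dose-response model suite --------------------------------------------

# Least-squares fit of one named model; returns NULL on failure.
fitOneModel <- function(model, d, y) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200L)
  a0 <- mean(y[d == 0])
  slope <- if (stats::var(d) > 0) stats::cov(d, y) / stats::var(d) else 0
  dat <- data.frame(d = d, y = y)
  out <- tryCatch(switch(model,
    linear = {
      fit <- stats::lm(y ~ d, data = dat)
      cf <- unname(stats::coef(fit))
      list(params = c(a = unname(cf[1]), b = unname(cf[2])), k = 2L,
           f = function(x) cf[1] + cf[2] * x)
    },
    poly2 = {
      fit <- stats::lm(y ~ d + I(d^2), data = dat)
      cf <- unname(stats::coef(fit))
      list(params = c(a = unname(cf[1]), b1 = unname(cf[2]),
                      b2 = unname(cf[3])), k = 3L,
           f = function(x) cf[1] + cf[2] * x + cf[3] * x^2)
    },
    poly3 = {
      fit <- stats::lm(y ~ d + I(d^2) + I(d^3), data = dat)
      cf <- unname(stats::coef(fit))
      list(params = c(a = unname(cf[1]), b1 = unname(cf[2]),
                      b2 = unname(cf[3]), b3 = unname(cf[4])), k = 4L,
           f = function(x) cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3)
    },
    power = {
      fit <- minpack.lm::nlsLM(y ~ a + b * d^p, data = dat,
                               start = list(a = a0, b = slope, p = 1),
                               lower = c(-Inf, -Inf, 0.1),
                               upper = c(Inf, Inf, 8), control = ctrl)
      cf <- stats::coef(fit)
      list(params = cf, k = 3L,
           f = function(x) cf[["a"]] + cf[["b"]] * x^cf[["p"]])
    },
    hill = {
      kw0 <- stats::median(d[d > 0])
      fit <- minpack.lm::nlsLM(y ~ a + b * d^n / (kk^n + d^n), data = dat,
                               start = list(a = a0, b = mean(y[d == max(d)]) - a0,
                                            kk = kw0, n = 2),
                               lower = c(-Inf, -Inf, 1e-6, 1),
                               upper = c(Inf, Inf, Inf, 18), control = ctrl)
      cf <- stats::coef(fit)
      list(params = cf, k = 4L,
           f = function(x) cf[["a"]] +
             cf[["b"]] * x^cf[["n"]] / (cf[["kk"]]^cf[["n"]] + x^cf[["n"]]))
    },
    exp2 = {
      fit <- minpack.lm::nlsLM(y ~ a * exp(b * d), data = dat,
                               start = list(a = a0, b = slope / max(a0, 1e-6)),
                               control = ctrl)
      cf <- stats::coef(fit)
      list(params = cf, k = 2L,
           f = function(x) cf[["a"]] * exp(cf[["b"]] * x))
    },
    exp3 = {
      fit <- minpack.lm::nlsLM(y ~ a * exp(b * d^cc), data = dat,
                               start = list(a = a0, b = slope / max(a0, 1e-6),
                                            cc = 1),
                               lower = c(-Inf, -Inf, 0.2),
                               upper = c(Inf, Inf, 8), control = ctrl)
      cf <- stats::coef(fit)
      list(params = cf, k = 3L,
           f = function(x) cf[["a"]] * exp(cf[["b"]] * x^cf[["cc"]]))
    },
    exp4 = {
      fit <- minpack.lm::nlsLM(y ~ a * (cc - (cc - 1) * exp(-b * d)),
                               data = dat,
                               start = list(a = a0, b = 1 / max(max(d), 1),
                                            cc = mean(y[d == max(d)]) / max(a0, 1e-6)),
                               lower = c(-Inf, 1e-6, 1e-6), control = ctrl)
      cf <- stats::coef(fit)
      list(params = cf, k = 3L,
           f = function(x) cf[["a"]] *
             (cf[["cc"]] - (cf[["cc"]] - 1) * exp(-cf[["b"]] * x)))
    },
    exp5 = {
      fit <- minpack.lm::nlsLM(y ~ a * (cc - (cc - 1) * exp(-(b * d)^g)),
                               data = dat,
                               start = list(a = a0, b = 1 / max(max(d), 1),
                                            cc = mean(y[d == max(d)]) / max(a0, 1e-6),
                                            g = 1),
                               lower = c(-Inf, 1e-6, 1e-6, 0.2),
                               upper = c(Inf, Inf, Inf, 8), control = ctrl)
      cf <- stats::coef(fit)
      list(params = cf, k = 4L,
           f = function(x) cf[["a"]] *
             (cf[["cc"]] - (cf[["cc"]] - 1) * exp(-(cf[["b"]] * x)^cf[["g"]])))
    },
    toxsigValidationError("unknown dose-response model '%s'", model)),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  resid <- y - out$f(d)
  if (any(!is.finite(resid))) return(NULL)
  out$rss <- sum(resid^2)
  n <- length(y)
  # RSS floored so numerically perfect fits tie on AIC and the
  # fewest-parameters tie-break decides between nested models
  out$aic <- n * log(max(out$rss, 1e-12) / n) + 2 * out$k
  out$model <- model
  out
}

#' The dose-response model suite
#' @export
DOSE_MODELS <- c("exp2", "exp3", "exp4", "exp5", "poly2", "poly3",
                 "linear", "power", "hill")

#' Fit the dose-response model suite to one gene
#'
#' Least-squares fits of the exponential (degrees 2--5), polynomial
#' (degrees 2--3), linear, power and Hill models.  Each converged fit
#' records its parameters, RSS and AIC (\code{n log(RSS/n) + 2k});
#' non-converging models are dropped.
#'
#' @param doses numeric dose per observation (>= 4 distinct levels).
#' @param response numeric expression values.
#' @param models subset of \code{DOSE_MODELS}.
#' @return named list of fits (possibly empty).
#' @export
fitDoseModels <- function(doses, response, models = DOSE_MODELS) {
  if (length(unique(doses)) < 4L)
    toxsigValidationError("at least 4 dose levels are required")
  ok <- is.finite(response)
  fits <- lapply(models, fitOneModel, d = doses[ok], y = response[ok])
  names(fits) <- models
  Filter(Negate(is.null), fits)
}

#' Pick the winning fit: minimal AIC, ties to fewest parameters
#' @param fits output of \code{\link{fitDoseModels}}.
#' @return a single fit, or NULL if none converged.
#' @export
selectBestFit <- function(fits) {
  if (length(fits) == 0L) return(NULL)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "k")
  best <- order(round(aic, 8), k)[1L]   # near-equal AIC -> parsimony
  fits[[best]]
}

#' Gene-level benchmark dose from a fitted curve
#'
#' The BMD is the smallest positive dose where the fitted response differs
#' from its control level by \code{bmrRelative} of that level:
#' \eqn{|f(d) - f(0)| = bmr |f(0)|}.  Solved in closed form for the linear
#' (\eqn{bmr |a/b|}) and power models, otherwise by bracketed root-finding
#' on \code{[0, maxDose]}.  Undefined (with a reason code) when the control
#' level is 0, the curve is flat, or no crossing occurs in range.
#'
#' @param fit a fit from \code{\link{fitDoseModels}}.
#' @param maxDose upper end of the tested dose range.
#' @param bmrRelative benchmark response as a fraction of the control
#'   level (default 0.10).
#' @return list with \code{bmd} (NA when undefined) and \code{reason}.
#' @export
geneBmd <- function(fit, maxDose, bmrRelative = 0.10) {
  f0 <- unname(fit$f(0))
  if (!is.finite(f0) || abs(f0) < 1e-10)
    return(list(bmd = NA_real_, reason = "zero_control"))
  target <- bmrRelative * abs(f0)
  if (fit$model == "linear") {
    b <- fit$params[["b"]]
    if (b == 0) return(list(bmd = NA_real_, reason = "flat"))
    return(list(bmd = target / abs(b), reason = "ok"))
  }
  if (fit$model == "power") {
    b <- fit$params[["b"]]
    if (b == 0) return(list(bmd = NA_real_, reason = "flat"))
    return(list(bmd = (target / abs(b))^(1 / fit$params[["p"]]),
                reason = "ok"))
  }
  g <- function(d) abs(fit$f(d) - f0) - target
  grid <- seq(0, maxDose, length.out = 512L)
  vals <- g(grid)
  cross <- which(vals[-1L] > 0 & vals[-length(vals)] <= 0)
  if (length(cross) == 0L)
    return(list(bmd = NA_real_, reason = "no_crossing"))
  root <- stats::uniroot(g, lower = grid[cross[1L]],
                         upper = grid[cross[1L] + 1L], tol = 1e-10)$root
  list(bmd = root, reason = "ok")
}

#' Treatment-group benchmark dose by pathway aggregation
#'
#' BMD-bearing genes are tested for enrichment in each pathway by a
#' one-sided Fisher's exact test against the full gene universe that
#' entered the ANOVA filter.  Significantly enriched pathways
#' (p < \code{pCutoff}) with more than \code{minGenes} BMD-bearing members
#' and more than \code{minCoverage} of their (in-universe) genes covered
#' are retained; each scores the mean of its members' BMDs and the group
#' BMD_t is the minimum score.  Undefined when no pathway passes.
#'
#' @param geneBmds named numeric vector of gene-level BMDs (NA = no BMD).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe gene universe for the enrichment background (default:
#'   names of \code{geneBmds}).
#' @param pCutoff Fisher p-value cutoff (default 0.05).
#' @param minGenes pathways need strictly more than this many BMD-bearing
#'   members (default 3).
#' @param minCoverage strictly-greater fraction of pathway genes covered
#'   (default 0.05).
#' @return list with \code{bmdt} (NA when undefined), \code{pathway},
#'   \code{pathwayGenes}, and the per-pathway \code{table}.
#' @export
groupBmdt <- function(geneBmds, collection, universe = names(geneBmds),
                      pCutoff = 0.05, minGenes = 3L, minCoverage = 0.05) {
  empty <- list(bmdt = NA_real_, pathway = NA_character_,
                pathwayGenes = character(0), table = NULL)
  if (length(collection@sets) == 0L) return(empty)
  bearing <- names(geneBmds)[!is.na(geneBmds)]
  rows <- lapply(names(collection@sets), function(nm) {
    inPath <- intersect(collection@sets[[nm]], universe)
    hits <- intersect(inPath, bearing)
    n11 <- length(hits)
    tab <- matrix(c(n11, length(inPath) - n11,
                    length(bearing) - n11,
                    length(universe) - length(inPath) - length(bearing) + n11),
                  nrow = 2L)
    p <- if (length(inPath) == 0L) 1 else
      stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(pathway = nm, n_genes = n11,
               coverage = if (length(inPath)) n11 / length(inPath) else 0,
               p_value = p,
               mean_bmd = if (n11) mean(geneBmds[hits]) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  pass <- tab$p_value < pCutoff & tab$n_genes > minGenes &
    tab$coverage > minCoverage
  if (!any(pass)) { empty$table <- tab; return(empty) }
  kept <- tab[pass, , drop = FALSE]
  best <- kept[which.min(kept$mean_bmd), ]
  list(bmdt = best$mean_bmd, pathway = best$pathway,
       pathwayGenes = intersect(collection@sets[[best$pathway]], bearing),
       table = tab)
}

#' Run the full benchmark-dose pipeline over treatment groups
#'
#' Per group: ANOVA prefilter, model-suite fit and AIC selection per
#' passing gene, gene-level BMD at the 10% benchmark response, and
#' pathway-aggregated group BMD_t.
#'
#' @param experiments named list of \linkS4class{DoseResponseExperiment}s.
#' @param collection a \linkS4class{GeneSetCollection} for aggregation.
#' @param fdrCutoff,bmrRelative,pCutoff,minGenes,minCoverage thresholds as
#'   in the stage functions.
#' @return a \linkS4class{BMDResult}.
#' @export
bmdAnalysis <- function(experiments, collection, fdrCutoff = 0.05,
                        bmrRelative = 0.10, pCutoff = 0.05, minGenes = 3L,
                        minCoverage = 0.05) {
  geneRows <- list()
  groupRows <- list()
  for (nm in names(experiments)) {
    ex <- experiments[[nm]]
    passing <- anovaPrefilter(ex, fdrCutoff)
    maxDose <- max(ex@doses)
    bmds <- setNames(rep(NA_real_, nrow(ex@values)), rownames(ex@values))
    for (g in passing) {
      fits <- fitDoseModels(ex@doses, ex@values[g, ])
      best <- selectBestFit(fits)
      if (is.null(best)) {
        geneRows[[length(geneRows) + 1L]] <-
          data.frame(group = nm, gene = g, model = NA_character_,
                     aic = NA_real_, bmd = NA_real_, reason = "no_fit")
        next
      }
      res <- geneBmd(best, maxDose, bmrRelative)
      bmds[g] <- res$bmd
      geneRows[[length(geneRows) + 1L]] <-
        data.frame(group = nm, gene = g, model = best$model, aic = best$aic,
                   bmd = res$bmd, reason = res$reason)
    }
    agg <- groupBmdt(bmds, collection, universe = rownames(ex@values),
                     pCutoff = pCutoff, minGenes = minGenes,
                     minCoverage = minCoverage)
    groupRows[[nm]] <- data.frame(group = nm, bmdt = agg$bmdt,
                                  pathway = agg$pathway,
                                  n_genes = length(agg$pathwayGenes))
  }
  new("BMDResult",
      geneTable = if (length(geneRows)) do.call(rbind, geneRows) else
        data.frame(group = character(0), gene = character(0),
                   model = character(0), aic = numeric(0), bmd = numeric(0),
                   reason = character(0)),
      groupTable = do.call(rbind, c(groupRows, list(make.row.names = FALSE))))
}

#' Concordance of transcriptomic and apical benchmark doses
#'
#' Pairs BMD_t and BMD_a by treatment group (dropping groups where either
#' is undefined), reports the mean BMD_t/BMD_a ratio and the Pearson
#' correlation of the log10-transformed pairs with its two-sided p-value
#' (linear scale with \code{logScale = FALSE}).
#'
#' @param bmdts,bmdas named numeric vectors of group-level benchmark doses.
#' @param logScale correlate log10 doses (default TRUE).
#' @return list with \code{n_defined}, \code{mean_ratio},
#'   \code{correlation}, \code{p_value}.
#' @export
concordance <- function(bmdts, bmdas, logScale = TRUE) {
  shared <- intersect(names(bmdts), names(bmdas))
  t <- bmdts[shared]
  a <- bmdas[shared]
  ok <- !is.na(t) & !is.na(a)
  t <- t[ok]
  a <- a[ok]
  n <- length(t)
  out <- list(n_defined = n,
              mean_ratio = if (n) mean(t / a) else NA_real_,
              correlation = NA_real_, p_value = NA_real_)
  if (n >= 3L) {
    ct <- if (logScale) stats::cor.test(log10(t), log10(a)) else
      stats::cor.test(t, a)
    out$correlation <- unname(ct$estimate)
    out$p_value <- ct$p.value
  }
  out
}
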