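mkExperiment <- function(values, doses, id = "toy") {
  new("DoseResponseExperiment", groupId = id, values = values, doses = doses)
}

test_that("the ANOVA prefilter keeps responders and passes everything at cutoff 1", {
  cfg <- simulationConfig(nGenes = 10L, nSamples = c(5L, 5L, 5L),
                          moduleSizes = 2L, nInformativeModules = 0L,
                          trueBmd = c(GENE0001 = 1, GENE0002 = 2),
                          doseNoiseSd = 0.1, seed = 21L)
  ex <- generateDoseResponse(cfg)
  passing <- anovaPrefilter(ex)
  expect_true(all(c("GENE0001", "GENE0002") %in% passing))
  expect_setequal(anovaPrefilter(ex, fdrCutoff = 1), rownames(ex@values))
  # a single-dose design cannot even be constructed
  flat <- matrix(rnorm(2 * 8), 2, dimnames = list(c("A", "B"), NULL))
  expect_error(mkExperiment(flat, rep(0, 8)), "dose levels")
})

test_that("noise-free linear data select the linear model and its closed-form BMD", {
  doses <- rep(c(0, 0.5, 1, 2, 4, 8), each = 3)
  y <- 10 + 2 * doses
  fits <- fitDoseModels(doses, y)
  best <- selectBestFit(fits)
  expect_lt(fits$linear$rss, 1e-18)
  expect_lte(fits$linear$aic, best$aic + 1e-9)
  res <- geneBmd(fits$linear, maxDose = 8)
  expect_equal(res$bmd, 0.5)                    # 0.1 * 10 / 2
  # and exactly 0.1 * |a/b| for random linear curves
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, 2, 20)
    b <- runif(1, -3, 3)
    if (abs(b) < 0.1) next
    f <- fitDoseModels(doses, a + b * doses, models = "linear")$linear
    expect_equal(geneBmd(f, maxDose = 8)$bmd, 0.1 * abs(a / b),
                 tolerance = 1e-9)
  }
})

test_that("Hill parameters and the planted BMD are recovered from clean data", {
  doses <- rep(c(0, 0.25, 0.5, 1, 2, 4, 8), each = 3)
  a <- 8; b <- 2.4; k <- 1.5 * sqrt(2); n <- 2
  y <- a + b * doses^n / (k^n + doses^n)
  fit <- fitDoseModels(doses, y, models = "hill")$hill
  expect_equal(unname(fit$params[["a"]]), a, tolerance = 0.01)
  expect_equal(unname(fit$params[["kk"]]), k, tolerance = 0.01)
  expect_equal(unname(fit$params[["n"]]), n, tolerance = 0.01)
  # BMD: |f(d) - a| = 0.1 * a = 0.8 -> d^2/(k^2+d^2) = 1/3 -> d = 1.5
  expect_equal(geneBmd(fit, maxDose = 8)$bmd, 1.5, tolerance = 0.001)

  # low noise: still within 5%
  set.seed(14)
  yn <- y + rnorm(length(y), sd = 0.05)
  fits <- fitDoseModels(doses, yn)
  best <- selectBestFit(fits)
  expect_equal(geneBmd(best, maxDose = 8)$bmd, 1.5, tolerance = 0.05)
})

test_that("AIC model choice is invariant to dose-unit rescaling and BMD rescales", {
  doses <- rep(c(0, 0.25, 0.5, 1, 2, 4), each = 3)
  set.seed(5)
  y <- 8 + 2.4 * doses^2 / (2 + doses^2) + rnorm(length(doses), sd = 0.05)
  b1 <- selectBestFit(fitDoseModels(doses, y))
  b2 <- selectBestFit(fitDoseModels(doses * 10, y))
  expect_identical(b1$model, b2$model)
  expect_equal(geneBmd(b2, maxDose = 40)$bmd,
               10 * geneBmd(b1, maxDose = 4)$bmd, tolerance = 0.01)
})

test_that("constant responses fall to the most parsimonious model, no BMD", {
  doses <- rep(c(0, 1, 2, 4), each = 3)
  y <- rep(5, length(doses))
  best <- selectBestFit(fitDoseModels(doses, y))
  expect_equal(best$k, 2L)                      # fewest-parameter tie-break
  res <- geneBmd(best, maxDose = 4)
  expect_true(is.na(res$bmd))
  # zero control level is undefined with a reason code
  f0 <- fitDoseModels(doses, 0 + 1 * doses, models = "linear")$linear
  expect_identical(geneBmd(f0, maxDose = 4)$reason, "zero_control")
})

test_that("pathway aggregation applies the strict count, coverage and p filters", {
  universe <- sprintf("G%03d", 1:100)
  bmds <- setNames(rep(NA_real_, 100), universe)
  bmds[1:10] <- c(2, 4, 3, 5, 1, 6, 2, 3, 8, 2)   # 10 BMD-bearing genes
  sets <- new("GeneSetCollection",
              sets = list(P_strong = universe[1:8],     # 8 bearing members
                          P_three = c(universe[c(1, 2, 3)], universe[90:95]),
                          P_none = universe[50:60]),
              family = rep("kegg", 3))
  out <- groupBmdt(bmds, sets, universe = universe)
  expect_identical(out$pathway, "P_strong")
  expect_equal(out$bmdt, mean(bmds[1:8]))
  tab <- out$table
  # 3 qualifying genes is excluded by the strict > rule
  expect_equal(tab$n_genes[tab$pathway == "P_three"], 3)
  expect_false(with(tab, n_genes[pathway == "P_three"] > 3))
  # one passing pathway with members (2, 4) -> mean 3
  one <- groupBmdt(setNames(c(2, 4, rep(NA, 58)), universe[1:60]),
                   new("GeneSetCollection",
                       sets = list(P = universe[1:2]), family = "kegg"),
                   universe = universe[1:60], minGenes = 1L)
  expect_equal(one$bmdt, 3)
  # two passing pathways -> the minimum of the means
  two <- groupBmdt(setNames(c(2, 4, 4, 6, rep(NA, 56)), universe[1:60]),
                   new("GeneSetCollection",
                       sets = list(Pa = universe[1:2], Pb = universe[3:4]),
                       family = c("kegg", "kegg")),
                   universe = universe[1:60], minGenes = 1L)
  expect_equal(two$bmdt, 3)
  # empty collection -> undefined
  none <- groupBmdt(bmds, new("GeneSetCollection", sets = list(),
                              family = character(0)))
  expect_true(is.na(none$bmdt))
})

test_that("concordance reports mean ratio and log-scale correlation", {
  t1 <- c(g1 = 1, g2 = 2, g3 = 4)
  out <- concordance(t1, t1)
  expect_equal(out$mean_ratio, 1)
  expect_equal(out$correlation, 1)
  expect_equal(out$n_defined, 3)
  r <- concordance(c(a = 2, b = 1), c(a = 1, b = 2))
  expect_equal(r$mean_ratio, mean(c(2, 0.5)))
  expect_true(is.na(r$correlation))            # < 3 pairs
})

test_that("group BMD_t converges to the minimum planted pathway mean at low noise", {
  cfg <- simulationConfig(nGenes = 120L, nSamples = c(10L, 10L, 10L),
                          moduleSizes = rep(20L, 3L), nPathways = 10L,
                          doseNoiseSd = 0.01, seed = 33L)
  b <- generateSyntheticBundle(cfg, nGroups = 1L)
  res <- bmdAnalysis(b@doseResponse, b@geneSets)
  got <- res@groupTable$bmdt[1]
  # oracle: replay the aggregation rules on the planted BMDs
  planted <- b@truth$trueBmd[[1]]
  universe <- rownames(b@doseResponse[[1]]@values)
  full <- setNames(rep(NA_real_, length(universe)), universe)
  full[names(planted)] <- planted
  oracle <- groupBmdt(full, b@geneSets, universe = universe)
  expect_false(is.na(got))
  expect_equal(got, oracle$bmdt, tolerance = 0.03)
})
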