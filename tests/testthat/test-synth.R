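smallCfg <- function(seed, ...) {
  simulationConfig(nCpgs = 1000L, nGenes = 200L, seed = seed, ...)
}

test_that("simulated dataset honours the dimension contract", {
  d <- simulateDataset(smallCfg(7))
  expect_equal(dim(betaValues(d$meth)), c(1000L, 6L))
  expect_equal(dim(detectionP(d$meth)), c(1000L, 6L))
  expect_equal(ncol(d$expr), 6L)
  expect_equal(nrow(d$expr), 200L)
  expect_equal(nrow(d$annotation), 1000L)
  expect_equal(nrow(d$truth$cpgs), 1000L)
  expect_true(all(betaValues(d$meth) >= 0 & betaValues(d$meth) <= 1))
  expect_equal(d$truth$cpgs$true_delta_beta,
               d$truth$cpgs$true_adult_mean - d$truth$cpgs$true_fetal_mean)
})

test_that("the same seed reproduces the dataset exactly", {
  d1 <- simulateDataset(smallCfg(7))
  d2 <- simulateDataset(smallCfg(7))
  expect_identical(betaValues(d1$meth), betaValues(d2$meth))
  expect_identical(exprValues(d1$expr), exprValues(d2$expr))
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$geneSets, d2$geneSets)
  d3 <- simulateDataset(smallCfg(8))
  expect_false(identical(betaValues(d1$meth), betaValues(d3$meth)))
})

test_that("a zero differential fraction yields a fully null methylome", {
  d <- simulateDataset(smallCfg(3, fracDiffCpgs = 0))
  expect_false(any(d$truth$cpgs$is_differential))
  expect_true(all(d$truth$cpgs$true_delta_beta == 0))
  expect_false(any(d$truth$genes$coupled))
})

test_that("within-group per-CpG variance sits at the configured ~1e-3 scale", {
  d <- simulateDataset(simulationConfig(nCpgs = 20000L, nGenes = 500L,
                                        fracDiffCpgs = 0, seed = 21))
  vs <- varianceSummary(d$meth)
  expect_true(all(vs$mean_variance > 5e-4 & vs$mean_variance < 2e-3))
  expect_true(all(vs$fraction_below > 0.95))
})

test_that("region labels follow the configured weights", {
  d <- simulateDataset(simulationConfig(nCpgs = 20000L, nGenes = 500L,
                                        fracUnannotated = 0, seed = 13))
  w <- c(TSS200 = 0.15, TSS1500 = 0.16, "5'UTR" = 0.14, "1stExon" = 0.08,
         Body = 0.42, "3'UTR" = 0.05)
  freq <- table(d$annotation$UCSC_RefGene_Group)[names(w)] / 20000
  tol <- 4 * sqrt(w * (1 - w) / 20000)
  expect_true(all(abs(freq - w) < tol))
})

test_that("the marginal beta distribution is bimodal when extremes dominate", {
  d <- simulateDataset(simulationConfig(
    nCpgs = 20000L, nGenes = 500L, fracDiffCpgs = 0,
    betaMixtureWeights = c(hypo = 0.45, intermediate = 0.1, hyper = 0.45),
    seed = 17))
  h <- betaHistogram(rowMeans(betaValues(d$meth)), binWidth = 0.05)
  central <- h$count[h$bin_start >= 0.25 & h$bin_end <= 0.75]
  expect_true(h$count[1] > max(central))
  expect_true(h$count[nrow(h)] > max(central))
})

test_that("coupled genes always carry a strong TSS/Ex1 methylation change", {
  d <- simulateDataset(smallCfg(29))
  coupled <- d$truth$genes$gene[d$truth$genes$coupled]
  expect_gt(length(coupled), 0L)
  tc <- d$truth$cpgs
  for (g in coupled) {
    sub <- tc[tc$gene == g & tc$region %in% c("TSS200", "TSS1500", "1stExon"), ]
    expect_true(any(abs(sub$true_delta_beta) > 0.2))
    # hyper -> intermediate pattern: fetal high, adult lower
    expect_true(all(sub$true_fetal_mean[abs(sub$true_delta_beta) > 0.2] >= 0.7))
  }
})

test_that("detection-p failures are injected at the configured rate", {
  d <- simulateDataset(smallCfg(31, detectionFailRate = 0.05))
  rate <- mean(detectionP(d$meth) > 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
  d0 <- simulateDataset(smallCfg(31, detectionFailRate = 0))
  expect_true(all(detectionP(d0$meth) < 0.05))
})

test_that("fixture directories round-trip losslessly", {
  dir <- withr::local_tempdir()
  d <- simulateDataset(smallCfg(41))
  writeFixture(d, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "beta.tsv", "detection_p.tsv", "expression.tsv", "annotation.tsv",
    "design.tsv", "truth.tsv")))))
  r <- readFixture(dir)
  expect_true(all(abs(betaValues(r$meth) - betaValues(d$meth)) < 1e-9))
  expect_true(all(abs(exprValues(r$expr) - exprValues(d$expr)) < 1e-9))
  expect_identical(r$annotation$UCSC_RefGene_Group,
                   d$annotation$UCSC_RefGene_Group)
  expect_equal(r$truth$cpgs$true_fetal_mean, d$truth$cpgs$true_fetal_mean,
               tolerance = 1e-9)
  expect_identical(sort(names(r$geneSets)), sort(names(d$geneSets)))
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(nCpgs = 100, seed = 1,
                                betaMixtureWeights = c(hypo = 0.5,
                                                       intermediate = 0.4,
                                                       hyper = 0.4)),
               "sum")
  expect_error(simulationConfig(nCpgs = 0, seed = 1), "positive")
  expect_error(simulationConfig(nCpgs = 100, seed = 1, fracDiffCpgs = 1.2),
               "fracDiffCpgs")
  expect_error(simulationConfig(nCpgs = 100), "seed")
})
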