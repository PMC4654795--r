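# Fixture: five CpGs on three genes with hand-chosen statistics.
fiveRowFixture <- function() {
  data.frame(
    cpg_id = c("cg01", "cg02", "cg03", "cg04", "cg05"),
    gene = c("G1", "G1", "G2", "G3", "G3"),
    region_class = c("TSS_EX1", "UTR_GB", "TSS_EX1", "UTR_GB", "TSS_EX1"),
    mean_fetal = c(0.85, 0.5, 0.2, 0.6, 0.4),
    mean_adult = c(0.35, 0.45, 0.25, 0.55, 0.45),
    delta_beta = c(-0.5, -0.05, 0.05, -0.05, 0.05),
    meth_q = c(0.01, 0.2, 0.01, 0.5, 0.04),
    expr_class = factor(c("ADULT_OVER", "ADULT_OVER", "SIMILAR", "OTHER",
                          "OTHER"),
                        levels = c("FETAL_OVER", "ADULT_OVER", "SIMILAR",
                                   "OTHER")),
    fold_change = c(-6, -6, 1.05, 1.5, 1.5),
    expr_q = c(0.01, 0.01, 0.6, 0.2, 0.2),
    stringsAsFactors = FALSE)
}

test_that("methylation levels use half-open bins with an inclusive top", {
  expect_equal(as.character(classifyMethLevel(c(0, 0.25, 0.299))),
               rep("HYPO", 3))
  expect_equal(as.character(classifyMethLevel(c(0.3, 0.5, 0.699))),
               rep("INTERMEDIATE", 3))
  expect_equal(as.character(classifyMethLevel(c(0.7, 0.9, 1))),
               rep("HYPER", 3))
  expect_error(classifyMethLevel(1.1), "0,1")
  b <- runif(200)
  expect_false(anyNA(classifyMethLevel(b)))   # total partition
})

test_that("expression classes partition genes by q, fold and similarity", {
  tab <- data.frame(gene = paste0("G", 1:6),
                    q_value = c(0.01, 0.01, 0.2, 0.01, 0.2, 0.01),
                    fold_change = c(6, -6, 1.05, 3, 2, 5))
  cls <- classifyExpression(tab)
  expect_equal(as.character(cls$expr_class),
               c("FETAL_OVER", "ADULT_OVER", "SIMILAR", "OTHER", "OTHER",
                 "FETAL_OVER"))
  expect_equal(sum(table(cls$expr_class)), 6L)   # total partition
})

test_that("relationship tables respect the filter definitions and hierarchy", {
  methDiff <- data.frame(
    cpg_id = c("cg01", "cg02", "cg03", "cg04", "cg05"),
    mean_fetal = c(0.9, 0.5, 0.3, 0.6, 0.2),
    mean_adult = c(0.4, 0.45, 0.35, 0.9, 0.21),
    delta_beta = c(-0.5, -0.05, 0.05, 0.3, 0.01),
    q_value = c(0.01, 0.01, 0.2, 0.01, 0.01))
  annot <- data.frame(
    IlmnID = methDiff$cpg_id, CHR = "1", MAPINFO = 1:5,
    UCSC_RefGene_Name = c("G1", "G2", "G2", "G3", "G4"),
    UCSC_RefGene_Group = c("TSS200", "Body", "TSS1500", "Body", "TSS200"),
    Regulatory_Feature_Group = "", stringsAsFactors = FALSE)
  links <- buildLinks(annot)
  exprDiff <- data.frame(gene = c("G1", "G2", "G3", "G4"),
                         fold_change = c(-6, 1.05, 2, 1.2))

  a <- relationshipTable(methDiff, links, exprDiff, qCut = 0.05)
  b <- relationshipTable(methDiff, links, exprDiff, qCut = 0.05,
                         minAbsDbeta = 0.2)
  cc <- relationshipTable(methDiff, links, exprDiff, qCut = 0.05,
                          region = "TSS_EX1")
  d <- relationshipTable(methDiff, links, exprDiff, qCut = 0.05,
                         minAbsDbeta = 0.2, region = "TSS_EX1")
  # panel a: every gene with >= 1 q-significant CpG
  expect_setequal(a$gene, c("G1", "G2", "G3", "G4"))
  # monotone filtering
  expect_true(all(d$gene %in% b$gene))
  expect_true(all(d$gene %in% cc$gene))
  expect_true(all(b$gene %in% a$gene))
  expect_true(all(cc$gene %in% a$gene))
  # panel d keeps only the TSS/Ex1 gene with |dbeta| > 0.2
  expect_equal(d$gene, "G1")
  expect_equal(d$mean_fetal, 0.9)
  expect_equal(d$fold_change, -6)

  # directional variant
  dInc <- relationshipTable(methDiff, links, exprDiff, qCut = 0.05,
                            minAbsDbeta = 0.2, directional = "increase")
  expect_equal(dInc$gene, "G3")
})

test_that("category tables count levels with half-up integer percentages", {
  rec <- fiveRowFixture()[rep(1, 10), ]
  rec$mean_fetal <- rep(0.1, 10)
  tab <- categoryTable(rec)
  row <- tab[tab$context == "ADULT_OVER" & tab$tissue == "fetal" &
               tab$region_class == "TSS_EX1", ]
  expect_equal(c(row$pct_hypo, row$pct_intermediate, row$pct_hyper),
               c(100, 0, 0))

  # 8 CpGs: 5 hypo, 2 intermediate, 1 hyper -> 63 / 25 / 13 after rounding
  rec8 <- fiveRowFixture()[rep(1, 8), ]
  rec8$cpg_id <- sprintf("cg%02d", 1:8)
  rec8$mean_fetal <- c(rep(0.1, 5), rep(0.5, 2), 0.9)
  tab8 <- categoryTable(rec8)
  row8 <- tab8[tab8$context == "ADULT_OVER" & tab8$tissue == "fetal" &
                 tab8$region_class == "TSS_EX1", ]
  expect_equal(c(row8$pct_hypo, row8$pct_intermediate, row8$pct_hyper),
               c(63, 25, 13))
  expect_equal(row8$n_cpgs, 8L)

  # empty stratum is flagged NA, not divided
  empty <- tab8[tab8$context == "FETAL_OVER" & tab8$tissue == "fetal" &
                  tab8$region_class == "TSS_EX1", ]
  expect_equal(empty$n_cpgs, 0L)
  expect_true(is.na(empty$pct_hypo))

  # counts equal an independent scan on random fixtures
  rec <- randomRecords(80, seed = 31)
  rec$fetal_level <- classifyMethLevel(rec$mean_fetal)
  rec$adult_level <- classifyMethLevel(rec$mean_adult)
  tab <- categoryTable(rec)
  for (k in sample(nrow(tab), 6)) {
    row <- tab[k, ]
    cnt <- bruteCategoryCounts(rec, row$context, row$tissue, row$region_class)
    expect_equal(c(row$n_hypo, row$n_intermediate, row$n_hyper),
                 unname(cnt))
  }
})

test_that("dedup flag counts multi-gene CpGs once", {
  rec <- fiveRowFixture()[c(1, 1), ]
  rec$gene <- c("G1", "G9")
  tab <- categoryTable(rec, dedupCpGs = TRUE)
  row <- tab[tab$context == "ADULT_OVER" & tab$tissue == "fetal" &
               tab$region_class == "TSS_EX1", ]
  expect_equal(row$n_cpgs, 1L)
})

test_that("chi-square matches hand computation and the 2x2 closed form", {
  res0 <- chiSquareTest(matrix(10, 2, 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  res <- chiSquareTest(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$statistic, 6.667, tolerance = 1e-4)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, 0.0098, tolerance = 1e-2)
  expect_false(res$low_expected)

  expect_error(chiSquareTest(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "marginal")
  expect_error(chiSquareTest(matrix(1:3, 1)), "2 x 2")

  expect_true(chiSquareTest(matrix(c(2, 3, 4, 1), 2))$low_expected)

  withr::with_seed(23, {
    for (i in 1:100) {
      tab <- matrix(rpois(4, 30) + 1, 2)
      expect_equal(chiSquareTest(tab)$statistic, bruteChi2x2(tab),
                   tolerance = 1e-12)
    }
  })
})

test_that("prediction probabilities equal a brute-force scan", {
  # 4 qualifying TSS/Ex1 decrease CpGs, exactly 1 on a >=2-fold adult gene
  rec <- data.frame(
    cpg_id = paste0("cg", 1:5),
    gene = paste0("G", 1:5),
    region_class = c(rep("TSS_EX1", 4), "UTR_GB"),
    mean_fetal = 0.8, mean_adult = 0.4,
    delta_beta = c(-0.4, -0.3, -0.5, -0.25, -0.4),
    meth_q = 0.01,
    expr_class = factor(rep("OTHER", 5),
                        levels = c("FETAL_OVER", "ADULT_OVER", "SIMILAR",
                                   "OTHER")),
    fold_change = c(-3, 1.1, 1.2, -1.5, -4),
    expr_q = 0.01, stringsAsFactors = FALSE)
  p <- predictionProbability(rec, "decrease", 0.2, "TSS_EX1")
  expect_equal(p$n_cpgs, 4L)
  expect_equal(p$prob_ge2, 0.25)
  expect_equal(p$prob_ge5, 0)

  # nested events: >=5-fold probability never exceeds >=2-fold
  for (s in 1:5) {
    r <- randomRecords(60, seed = 100 + s)
    for (dir in c("decrease", "increase")) for (rg in c("TSS_EX1", "UTR_GB")) {
      got <- predictionProbability(r, dir, 0.2, rg)
      ref <- brutePredProb(r, dir, 0.2, rg)
      expect_equal(got$n_cpgs, ref$n)
      expect_equal(c(got$prob_ge2, got$prob_ge5), ref$probs)
      if (!is.na(got$prob_ge2)) expect_lte(got$prob_ge5, got$prob_ge2)
    }
  }

  # zero qualifying CpGs -> flagged empty, not zero
  none <- predictionProbability(rec, "increase", 0.5, "UTR_GB")
  expect_equal(none$n_cpgs, 0L)
  expect_true(is.na(none$prob_ge2))
})

test_that("density summaries integrate to one and localize point masses", {
  rec <- fiveRowFixture()
  dens <- densitySummary(rec, stratifyBy = "region_class",
                         contexts = "ADULT_OVER")
  one <- dens[dens$tissue == "fetal" & dens$stratum == "TSS_EX1", ]
  expect_equal(sum(one$density * 0.05), 1, tolerance = 1e-12)
  # single value 0.85 -> unit mass in bin [0.85, 0.90)
  expect_equal(one$density[abs(one$bin_start - 0.85) < 1e-9], 20)
  expect_equal(sum(one$density > 0), 1L)

  u <- randomRecords(4000, seed = 77)
  du <- densitySummary(u, stratifyBy = "region_class", contexts = "SIMILAR")
  sub <- du[du$tissue == "adult" & du$stratum == "TSS_EX1", ]
  expect_equal(sum(sub$density * 0.05), 1, tolerance = 1e-12)
  expect_true(all(abs(sub$density - 1) < 0.5))   # roughly flat for uniforms
})

test_that("integration records join methylation and expression consistently", {
  d <- simulateDataset(simulationConfig(nCpgs = 2000, nGenes = 300, seed = 55))
  m <- filterSexChromosomes(filterDetection(d$meth))
  dm <- diffMethylation(m)
  de <- diffExpression(d$expr)
  links <- buildLinks(cpgAnnotation(m))
  cls <- classifyExpression(de)
  rec <- integrationRecords(dm, links, cls)
  expect_true(all(rec$region_class %in% c("TSS_EX1", "UTR_GB")))
  i <- match(rec$cpg_id, dm$cpg_id)
  expect_equal(rec$delta_beta, dm$delta_beta[i])
  j <- match(rec$gene, cls$gene)
  expect_equal(as.character(rec$expr_class), as.character(cls$expr_class[j]))
  expect_equal(as.character(rec$fetal_level),
               as.character(classifyMethLevel(rec$mean_fetal)))
})
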