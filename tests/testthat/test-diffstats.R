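mkBeta <- function(values, nProbes = NULL) {
  m <- matrix(values, ncol = 6, byrow = TRUE)
  rownames(m) <- sprintf("cg%02d", seq_len(nrow(m)))
  colnames(m) <- toyDesign()$sample_id
  m
}

test_that("detection filter keeps only probes passing in every sample", {
  b <- mkBeta(rep(0.5, 18))
  dp <- mkBeta(c(rep(0.001, 6), c(0.001, 0.2, 0.001, 0.001, 0.001, 0.001),
                 rep(0.04, 6)))
  me <- toyMeth(b, detp = dp)
  f <- filterDetection(me, 0.05)
  expect_setequal(rownames(f), c("cg01", "cg03"))
  expect_equal(metadata(f)$n_removed_detection, 1L)

  empty <- me[integer(0), ]
  fe <- filterDetection(empty, 0.05)
  expect_equal(nrow(fe), 0L)
  expect_equal(metadata(fe)$n_removed_detection, 0L)

  expect_error(filterDetection(toyMeth(b), 0.05), "detectionP")
})

test_that("sex-chromosome filter normalizes chr prefixes and demands annotation", {
  annot <- toyAnnotation()
  b <- mkBeta(rep(0.5, 30))
  rownames(b) <- annot$IlmnID
  me <- toyMeth(b, annot = annot)
  f <- filterSexChromosomes(me)
  expect_setequal(rownames(f), c("cg01", "cg02", "cg05"))  # X and chrY removed
  expect_equal(metadata(f)$n_removed_sex, 2L)

  auto <- me[c("cg01", "cg02"), ]
  expect_equal(nrow(filterSexChromosomes(auto)), 2L)

  annot2 <- annot; annot2$CHR[1] <- ""
  me2 <- toyMeth(b, annot = annot2)
  expect_error(filterSexChromosomes(me2), "cg01")
})

test_that("logit transform matches its closed form and stays finite", {
  expect_equal(logitTransform(0.5, offset = 0), 0)
  expect_equal(logitTransform(0.8, offset = 0), 2)           # log2(4)
  m0 <- logitTransform(0, offset = 1e-6)
  expect_true(is.finite(m0))
  expect_equal(m0, log2(1e-6 / (1 + 1e-6)), tolerance = 1e-12)
  expect_equal(m0, -19.93, tolerance = 1e-3)
  expect_true(all(is.finite(logitTransform(c(0, 1, 0.25), offset = 1e-6))))
  expect_error(logitTransform(1.2), "0,1")
})

test_that("the per-feature group model reproduces hand OLS", {
  m <- mkBeta(c(1, 2, 3, 4, 5, 6))
  fit <- fitGroupModel(m, toyDesign())
  expect_equal(fit$effect, 3)
  expect_equal(fit$s2, 1)
  expect_equal(fit$df, 4)
  expect_equal(fit$leverage, 2 / 3)

  same <- fitGroupModel(mkBeta(c(1, 2, 3, 1, 2, 3)), toyDesign())
  expect_equal(same$effect, 0)

  const <- fitGroupModel(mkBeta(rep(0.4, 6)), toyDesign())
  expect_equal(const$s2, 0)
  expect_true(const$zero_variance)
})

test_that("covariate designs agree with lm and reject rank deficiency", {
  set.seed(4)
  des <- toyDesign()
  des$age <- c(1, 2, 3, 10, 11, 12)
  y <- rnorm(6)
  m <- matrix(y, 1, dimnames = list("f1", des$sample_id))
  fit <- fitGroupModel(m, des)
  ref <- lm(y ~ group + age, data = transform(des, group = factor(group,
            c("fetal", "adult"))))
  expect_equal(fit$effect, unname(coef(ref)["groupadult"]), tolerance = 1e-10)
  expect_equal(fit$s2, sum(residuals(ref)^2) / ref$df.residual,
               tolerance = 1e-10)
  expect_equal(fit$df, ref$df.residual)

  des$dupe <- ifelse(des$group == "adult", 1, 0)   # aliases the group column
  expect_error(fitGroupModel(m, des), "rank-deficient")
})

test_that("variance moderation has the no-spread and no-prior limits", {
  eq <- moderateVariances(rep(0.7, 10), df = 4)
  expect_true(is.infinite(eq$d0))
  expect_equal(eq$posterior, rep(0.7, 10), tolerance = 1e-12)

  s2 <- c(0.5, 1, 2, 4)
  expect_equal(posteriorVariance(s2, 4, d0 = 0, s20 = 1), s2)
  expect_equal(posteriorVariance(s2, 4, d0 = Inf, s20 = 1), rep(1, 4))

  expect_error(moderateVariances(c(0, 0), df = 4), "at least 2")
})

test_that("posterior variances are convex combinations of prior and sample", {
  withr::with_seed(11, {
    s2 <- 0.05 * stats::rf(500, 4, 4)
    mod <- moderateVariances(s2, df = 4)
    lo <- pmin(mod$s20, s2); hi <- pmax(mod$s20, s2)
    expect_true(all(mod$posterior >= lo - 1e-12 & mod$posterior <= hi + 1e-12))
  })
})

test_that("moderation recovers known prior parameters from scaled-F variances", {
  withr::with_seed(42, {
    d0 <- 4; s20 <- 0.05; df <- 4
    s2 <- s20 * (stats::rchisq(5000, df) / df) / (stats::rchisq(5000, d0) / d0)
    mod <- moderateVariances(s2, df = df)
    expect_lt(abs(mod$d0 - d0) / d0, 0.2)
    expect_lt(abs(mod$s20 - s20) / s20, 0.1)
  })
})

test_that("the unmoderated test equals the classical two-sample t-test", {
  m <- mkBeta(c(1, 2, 3, 4, 5, 6))
  fit <- fitGroupModel(m, toyDesign())
  tst <- moderatedTest(fit, NULL)
  ref <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(tst$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tst$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(tst$t, 3.674235, tolerance = 1e-6)
  expect_equal(tst$p_value, 0.0213, tolerance = 1e-3)
})

test_that("moderated t has zero-effect and variance-scaling behaviour", {
  fit <- data.frame(effect = c(0, 2, 2), s2 = c(1, 1, 2), df = 4,
                    leverage = 2 / 3)
  tst <- moderatedTest(fit, NULL)
  expect_equal(tst$t[1], 0)
  expect_equal(tst$p_value[1], 1)
  expect_equal(tst$t[2] / tst$t[3], sqrt(2), tolerance = 1e-12)
})

test_that("the moderated pipeline agrees with the reference limma implementation", {
  skip_if_not_installed("limma")
  withr::with_seed(5, {
    m <- matrix(rnorm(600 * 6, sd = rep(sqrt(0.05 * stats::rf(600, 4, 4)),
                                        6)), ncol = 6)
    dimnames(m) <- list(sprintf("f%03d", 1:600), toyDesign()$sample_id)
  })
  fit <- fitGroupModel(m, toyDesign())
  mod <- moderateVariances(fit$s2, fit$df)
  tst <- moderatedTest(fit, mod)

  X <- cbind(1, rep(c(0, 1), each = 3))
  ref <- limma::eBayes(limma::lmFit(m, X))
  expect_equal(mod$d0, unname(ref$df.prior), tolerance = 1e-8)
  expect_equal(mod$s20, unname(ref$s2.prior), tolerance = 1e-8)
  expect_equal(tst$t, unname(ref$t[, 2]), tolerance = 1e-10)
  expect_equal(tst$p_value, unname(ref$p.value[, 2]), tolerance = 1e-10)
})

test_that("BH q-values match the definitional oracle and worked examples", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(0.5), 0.5)
  expect_equal(bhFDR(c(1e-4, 0.9)), c(2e-4, 0.9))
  expect_error(bhFDR(c(0.5, 1.3)), "0,1")
  withr::with_seed(9, {
    for (i in 1:200) {
      p <- runif(sample(1:200, 1))
      expect_equal(bhFDR(p), bruteBH(p), tolerance = 1e-14)
    }
  })
})

test_that("signed fold changes follow the +r / -1/r convention", {
  expect_equal(signedFoldChange(8, 5), 8)
  expect_equal(signedFoldChange(5, 8), -8)
  expect_equal(signedFoldChange(7, 7), 1)
  expect_true(all(abs(signedFoldChange(rnorm(50), rnorm(50))) >= 1))
})

test_that("variance summary computes the hand example", {
  b <- mkBeta(c(0.1, 0.2, 0.3, 0.5, 0.5, 0.5))
  vs <- varianceSummary(toyMeth(b))
  expect_equal(vs$mean_variance[vs$group == "fetal"], 0.01)
  expect_equal(vs$mean_variance[vs$group == "adult"], 0)
  b2 <- mkBeta(rep(c(0.4, 0.5, 0.6), 2))   # per-group variance 0.01 > 0.005
  vs2 <- varianceSummary(toyMeth(b2), cutoff = 0.02)
  expect_equal(vs2$fraction_below, c(1, 1))
})

test_that("beta histograms use left-closed bins with a closed last bin", {
  h <- betaHistogram(numeric(0))
  expect_equal(nrow(h), 20L)
  expect_true(all(h$count == 0))
  h2 <- betaHistogram(c(0, 0.049, 0.05))
  expect_equal(h2$count[1:2], c(2L, 1L))
  expect_equal(sum(h2$count), 3L)
  expect_equal(betaHistogram(1)$count[20], 1L)
  expect_error(betaHistogram(c(0.5, 1.2)), "outside")
  hd <- betaHistogram(c(-0.3, 0.99), binWidth = 0.05, range = c(-1, 1))
  expect_equal(nrow(hd), 40L)
  expect_equal(sum(hd$count), 2L)
})

test_that("differential methylation reports beta-scale effects with M-scale tests", {
  d <- simulateDataset(simulationConfig(nCpgs = 500, nGenes = 100, seed = 2))
  dm <- diffMethylation(d$meth)
  expect_equal(nrow(dm), 500L)
  expect_true(all(dm$delta_beta >= -1 & dm$delta_beta <= 1))
  expect_equal(dm$delta_beta, dm$mean_adult - dm$mean_fetal)
  expect_true(all(dm$q_value >= 0 & dm$q_value <= 1))
  # sorted q is monotone in sorted p
  o <- order(dm$p_value)
  expect_true(all(diff(dm$q_value[o]) >= -1e-15))
})
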