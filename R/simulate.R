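#' Simulation configuration
#'
#' Parameters of the two-group methylation + expression generator. Defaults
#' emulate a small two-group (3 vs 3) 450K-style study: a bimodal marginal
#' beta distribution with most probes hypo- or hypermethylated, within-group
#' per-CpG variance on the order of 1e-3, a large fraction of modestly
#' differential CpGs whose delta-beta spectrum is peaked near small values
#' and skewed toward higher adult methylation, manifest-style region labels,
#' a small sex-chromosome fraction, and a subset of adult-overexpressed
#' genes whose promoter/first-exon CpGs transition from fetal
#' hypermethylation to intermediate adult methylation.
#'
#' @slot nCpgs number of CpG probes
#' @slot nGenes number of genes
#' @slot samplesPerGroup samples per group (default 3, i.e. triplicates)
#' @slot betaMixtureWeights proportions of hypo/intermediate/hyper baseline
#'   modes (named, sum to 1)
#' @slot withinGroupPrecision concentration kappa of the per-CpG
#'   Beta(mu*kappa, (1-mu)*kappa) noise law; per-CpG variance is
#'   mu(1-mu)/(kappa+1), so the default 120 gives a mean variance near 1e-3
#'   under the default mixture
#' @slot fracDiffCpgs fraction of CpGs with a true group difference
#' @slot dbetaEffect list describing the signed effect-size law:
#'   \code{type} ("exponential" or "fixed"), \code{mean} or \code{value}
#'   (magnitude, beta scale), \code{probAdultHigher} (probability the adult
#'   mean is the higher one)
#' @slot regionLabelWeights proportions over the six RefGene groups (named)
#' @slot fracUnannotated fraction of probes with no gene annotation
#' @slot fracRegulatory fraction of probes with a regulatory-feature-group
#'   annotation; \code{fracPromoterAssoc} of those are "Promoter_Associated"
#' @slot fracPromoterAssoc see above
#' @slot fracSexChrom fraction of probes placed on chromosome X or Y
#' @slot couplingSpec list: \code{fracAdultOverCoupled} (fraction of genes
#'   adult-overexpressed with coupled fetal TSS/Ex1 hypermethylation),
#'   \code{fracFetalOver} (fraction fetal-overexpressed, expression only),
#'   \code{exprEffectLog2} (log2 expression effect size)
#' @slot exprNoiseSd per-sample expression noise SD (log2 units)
#' @slot detectionFailRate per-cell probability of a failed detection
#'   p-value (> 0.05)
#' @slot seed mandatory RNG seed; the same seed reproduces the dataset
#'   exactly
#' @export
setClass("SimulationConfig", representation(
  nCpgs = "integer", nGenes = "integer", samplesPerGroup = "integer",
  betaMixtureWeights = "numeric", withinGroupPrecision = "numeric",
  fracDiffCpgs = "numeric", dbetaEffect = "list",
  regionLabelWeights = "numeric", fracUnannotated = "numeric",
  fracRegulatory = "numeric", fracPromoterAssoc = "numeric",
  fracSexChrom = "numeric", couplingSpec = "list", exprNoiseSd = "numeric",
  detectionFailRate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chkProp <- function(x, nm) if (any(x < 0 | x > 1))
    sprintf("%s must lie in [0,1]", nm) else NULL
  if (object@nCpgs < 1L || object@nGenes < 1L || object@samplesPerGroup < 2L)
    msg <- c(msg, "counts must be positive (>= 2 samples per group)")
  w <- object@betaMixtureWeights
  if (!identical(sort(names(w)), sort(c("hypo", "intermediate", "hyper"))) ||
      abs(sum(w) - 1) > 1e-8 || any(w < 0))
    msg <- c(msg, "betaMixtureWeights must be named hypo/intermediate/hyper, non-negative, summing to 1")
  rw <- object@regionLabelWeights
  if (!identical(sort(names(rw)), sort(REFGENE_GROUPS)) ||
      abs(sum(rw) - 1) > 1e-8 || any(rw < 0))
    msg <- c(msg, "regionLabelWeights must cover the six RefGene groups and sum to 1")
  if (object@withinGroupPrecision <= 0)
    msg <- c(msg, "withinGroupPrecision must be positive")
  for (nm in c("fracDiffCpgs", "fracUnannotated", "fracRegulatory",
               "fracPromoterAssoc", "fracSexChrom", "detectionFailRate")) {
    m <- chkProp(slot(object, nm), nm); if (!is.null(m)) msg <- c(msg, m)
  }
  cs <- object@couplingSpec
  if (!all(c("fracAdultOverCoupled", "fracFetalOver", "exprEffectLog2") %in%
           names(cs)) ||
      cs$fracAdultOverCoupled < 0 || cs$fracAdultOverCoupled > 1 ||
      cs$fracFetalOver < 0 || cs$fracFetalOver > 1)
    msg <- c(msg, "couplingSpec needs fracAdultOverCoupled, fracFetalOver in [0,1] and exprEffectLog2")
  de <- object@dbetaEffect
  if (!de$type %in% c("exponential", "fixed") ||
      (de$type == "exponential" && is.null(de$mean)) ||
      (de$type == "fixed" && is.null(de$value)))
    msg <- c(msg, "dbetaEffect must be list(type='exponential', mean=..) or list(type='fixed', value=..)")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nCpgs,nGenes,samplesPerGroup,betaMixtureWeights,withinGroupPrecision
#'   see slots
#' @param fracDiffCpgs,dbetaEffect,regionLabelWeights,fracUnannotated see slots
#' @param fracRegulatory,fracPromoterAssoc,fracSexChrom,couplingSpec see slots
#' @param exprNoiseSd,detectionFailRate,seed see slots
#' @export
simulationConfig <- function(
    nCpgs = 10000L, nGenes = 2000L, samplesPerGroup = 3L,
    betaMixtureWeights = c(hypo = 0.35, intermediate = 0.25, hyper = 0.40),
    withinGroupPrecision = 120,
    fracDiffCpgs = 0.4,
    dbetaEffect = list(type = "exponential", mean = 0.12,
                       probAdultHigher = 0.72),
    regionLabelWeights = c(TSS200 = 0.15, TSS1500 = 0.16, "5'UTR" = 0.14,
                           "1stExon" = 0.08, Body = 0.42, "3'UTR" = 0.05),
    fracUnannotated = 0.25, fracRegulatory = 0.21, fracPromoterAssoc = 0.6,
    fracSexChrom = 0.025,
    couplingSpec = list(fracAdultOverCoupled = 0.05, fracFetalOver = 0.05,
                        exprEffectLog2 = 3),
    exprNoiseSd = 0.25, detectionFailRate = 0.001, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(dbetaEffect$probAdultHigher))
    dbetaEffect$probAdultHigher <- 0.72
  new("SimulationConfig", nCpgs = as.integer(nCpgs),
      nGenes = as.integer(nGenes),
      samplesPerGroup = as.integer(samplesPerGroup),
      betaMixtureWeights = betaMixtureWeights,
      withinGroupPrecision = withinGroupPrecision,
      fracDiffCpgs = fracDiffCpgs, dbetaEffect = dbetaEffect,
      regionLabelWeights = regionLabelWeights,
      fracUnannotated = fracUnannotated, fracRegulatory = fracRegulatory,
      fracPromoterAssoc = fracPromoterAssoc, fracSexChrom = fracSexChrom,
      couplingSpec = couplingSpec, exprNoiseSd = exprNoiseSd,
      detectionFailRate = detectionFailRate, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d CpGs, %d genes, %d vs %d samples, seed %d\n",
    object@nCpgs, object@nGenes, object@samplesPerGroup,
    object@samplesPerGroup, object@seed))
  cat(sprintf("  fracDiffCpgs %.3g, kappa %.4g, coupling %.3g/%.3g\n",
              object@fracDiffCpgs, object@withinGroupPrecision,
              object@couplingSpec$fracAdultOverCoupled,
              object@couplingSpec$fracFetalOver))
})

.clipBeta <- function(x) pmin(pmax(x, 0.01), 0.99)

#' Simulate a two-group methylation + expression dataset with ground truth
#'
#' Draws per-CpG fetal baseline means from a hypo/intermediate/hyper
#' mixture, applies signed mean-scale effects (clipped to [0.01, 0.99]) to a
#' configured fraction of CpGs to form the adult means, and samples beta
#' values from Beta(mu*kappa, (1-mu)*kappa) noise. A configured fraction of
#' genes is made adult-overexpressed with coupled promoter/first-exon
#' methylation: their TSS/Ex1 CpGs transition from fetal hypermethylation
#' (mean in [0.75, 0.98]) to low-intermediate adult methylation
#' ([0.30, 0.50]), guaranteeing |true delta beta| > 0.2, while the gene
#' gains an adult expression effect. Fetal-overexpressed genes receive an
#' expression effect only. With \code{fracDiffCpgs = 0} the methylome is
#' fully null: no coupled genes are created and every true delta beta is 0.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return list with \code{meth} (\linkS4class{MethylExperiment} with beta,
#'   detectionP, annotation), \code{expr} (\linkS4class{ExprExperiment}),
#'   \code{design} (data.frame), \code{annotation} (data.frame),
#'   \code{truth} (list with \code{cpgs} and \code{genes} data.frames) and
#'   \code{geneSets} (named list for the enrichment stage)
#' @export
simulateDataset <- function(config) {
  validObject(config)
  withSeed(config@seed, .simulateDataset(config))
}

.simulateDataset <- function(config) {
  n <- config@nCpgs; nG <- config@nGenes; spg <- config@samplesPerGroup
  cpgIds <- sprintf("cg%08d", seq_len(n))
  geneIds <- sprintf("GENE%05d", seq_len(nG))
  samples <- c(paste0("F", seq_len(spg)), paste0("A", seq_len(spg)))
  design <- data.frame(sample_id = samples,
                       group = rep(c("fetal", "adult"), each = spg),
                       stringsAsFactors = FALSE)

  # --- annotation -----------------------------------------------------------
  sex <- stats::runif(n) < config@fracSexChrom
  chrom <- ifelse(sex, sample(c("X", "Y"), n, replace = TRUE),
                  as.character(sample.int(22L, n, replace = TRUE)))
  annotated <- stats::runif(n) >= config@fracUnannotated
  gene <- ifelse(annotated, sample(geneIds, n, replace = TRUE), "")
  region <- ifelse(annotated,
                   sample(names(config@regionLabelWeights), n, replace = TRUE,
                          prob = config@regionLabelWeights), "")
  hasReg <- stats::runif(n) < config@fracRegulatory
  regFeat <- ifelse(hasReg,
                    ifelse(stats::runif(n) < config@fracPromoterAssoc,
                           "Promoter_Associated",
                           "Unclassified_Cell_type_specific"), "")
  annot <- data.frame(IlmnID = cpgIds, CHR = chrom,
                      MAPINFO = sample.int(2.4e8, n, replace = TRUE),
                      UCSC_RefGene_Name = gene, UCSC_RefGene_Group = region,
                      Regulatory_Feature_Group = regFeat,
                      stringsAsFactors = FALSE)

  # --- baseline fetal means -------------------------------------------------
  mode <- sample(names(config@betaMixtureWeights), n, replace = TRUE,
                 prob = config@betaMixtureWeights)
  muF <- numeric(n)
  nh <- sum(mode == "hypo")
  muF[mode == "hypo"] <- pmin(pmax(stats::rbeta(nh, 1.2, 12), 0.01), 0.4)
  ni <- sum(mode == "intermediate")
  muF[mode == "intermediate"] <- stats::runif(ni, 0.35, 0.65)
  nj <- sum(mode == "hyper")
  muF[mode == "hyper"] <- 1 - pmin(pmax(stats::rbeta(nj, 1.2, 12), 0.01), 0.4)

  # --- differential effects -------------------------------------------------
  muA <- muF
  isDiff <- logical(n)
  coupled <- character(0)
  fetalOver <- character(0)
  if (config@fracDiffCpgs > 0) {
    nd <- round(config@fracDiffCpgs * n)
    di <- sample.int(n, nd)
    de <- config@dbetaEffect
    mag <- if (de$type == "fixed") rep(de$value, nd) else
      pmin(stats::rexp(nd, rate = 1 / de$mean), 0.6)
    upOk <- muF[di] + mag <= 0.99
    dnOk <- muF[di] - mag >= 0.01
    wantUp <- stats::runif(nd) < de$probAdultHigher
    up <- (upOk & (wantUp | !dnOk)) | (!upOk & !dnOk)
    muA[di] <- .clipBeta(muF[di] + ifelse(up, mag, -mag))
    isDiff[di] <- muA[di] != muF[di]

    # --- expression coupling ------------------------------------------------
    cs <- config@couplingSpec
    tssAuto <- annotated & region %in% TSS_EX1_GROUPS & !sex
    eligible <- unique(gene[tssAuto])
    nCoupled <- min(round(cs$fracAdultOverCoupled * nG), length(eligible))
    if (nCoupled > 0) {
      coupled <- sample(eligible, nCoupled)
      ci <- which(tssAuto & gene %in% coupled)
      muF[ci] <- stats::runif(length(ci), 0.75, 0.98)
      muA[ci] <- stats::runif(length(ci), 0.30, 0.50)
      isDiff[ci] <- TRUE
    }
    nFo <- round(cs$fracFetalOver * nG)
    pool <- setdiff(geneIds, coupled)
    if (nFo > 0) fetalOver <- sample(pool, min(nFo, length(pool)))
  }

  # --- beta and detection-p draws -------------------------------------------
  kap <- config@withinGroupPrecision
  # beta noise: shape1 = mu*kappa, shape2 = (1-mu)*kappa, variance
  # mu(1-mu)/(kappa+1)
  betaF <- matrix(stats::rbeta(n * spg, rep(muF, spg) * kap,
                               (1 - rep(muF, spg)) * kap), nrow = n)
  betaA <- matrix(stats::rbeta(n * spg, rep(muA, spg) * kap,
                               (1 - rep(muA, spg)) * kap), nrow = n)
  beta <- cbind(betaF, betaA)
  dimnames(beta) <- list(cpgIds, samples)
  detp <- matrix(stats::runif(n * 2 * spg, 0, 0.005), nrow = n,
                 dimnames = dimnames(beta))
  fail <- stats::runif(n * 2 * spg) < config@detectionFailRate
  detp[fail] <- stats::runif(sum(fail), 0.051, 1)

  # --- expression -----------------------------------------------------------
  base <- stats::rnorm(nG, 7, 1.5)
  eff <- config@couplingSpec$exprEffectLog2
  meanF <- base + ifelse(geneIds %in% fetalOver, eff, 0)
  meanA <- base + ifelse(geneIds %in% coupled, eff, 0)
  exprs <- cbind(
    matrix(stats::rnorm(nG * spg, rep(meanF, spg), config@exprNoiseSd),
           nrow = nG),
    matrix(stats::rnorm(nG * spg, rep(meanA, spg), config@exprNoiseSd),
           nrow = nG))
  dimnames(exprs) <- list(geneIds, samples)

  # --- truth ----------------------------------------------------------------
  truthCpgs <- data.frame(
    cpg_id = cpgIds, chromosome = chrom, gene = gene, region = region,
    true_fetal_mean = muF, true_adult_mean = muA,
    true_delta_beta = muA - muF, is_differential = isDiff,
    stringsAsFactors = FALSE)
  geneClass <- ifelse(geneIds %in% coupled, "ADULT_OVER",
                      ifelse(geneIds %in% fetalOver, "FETAL_OVER",
                             "BACKGROUND"))
  truthGenes <- data.frame(
    gene = geneIds, true_log2_diff = meanF - meanA,
    expression_class = geneClass, coupled = geneIds %in% coupled,
    stringsAsFactors = FALSE)

  # --- demonstration gene-set collection ------------------------------------
  geneSets <- list()
  mkset <- function(core, size) unique(c(core, sample(geneIds, size)))
  if (length(coupled))
    geneSets$adult_induction_module <- mkset(coupled, 10L)
  if (length(fetalOver))
    geneSets$fetal_growth_module <- mkset(fetalOver, 10L)
  for (i in 1:3)
    geneSets[[paste0("random_module_", i)]] <-
      sample(geneIds, min(25L, nG))

  meth <- MethylExperiment(beta, design, detectionP = detp,
                           annotation = annot)
  expr <- ExprExperiment(exprs, design)
  list(meth = meth, expr = expr, design = design, annotation = annot,
       truth = list(cpgs = truthCpgs, genes = truthGenes),
       geneSets = geneSets)
}

#' Write a simulated dataset as a fixture directory
#'
#' Emits the TSV files the pipeline readers consume (beta.tsv,
#' detection_p.tsv, expression.tsv, annotation.tsv, design.tsv, truth.tsv)
#' plus truth_genes.tsv and gene_sets.gmt.
#'
#' @param dataset list from \code{\link{simulateDataset}}
#' @param dir output directory (created if absent)
#' @return invisibly, the named vector of file paths
#' @export
writeFixture <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             detection_p = file.path(dir, "detection_p.tsv"),
             expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"))
  writeArrayMatrix(betaValues(dataset$meth), paths["beta"])
  writeArrayMatrix(detectionP(dataset$meth), paths["detection_p"])
  writeArrayMatrix(assay(dataset$expr, "exprs"), paths["expression"])
  writeCpGAnnotation(dataset$annotation, paths["annotation"])
  writeSampleDesign(dataset$design, paths["design"])
  tc <- dataset$truth$cpgs[, c("cpg_id", "true_fetal_mean",
                               "true_adult_mean", "true_delta_beta",
                               "is_differential", "region", "gene",
                               "chromosome")]
  utils::write.table(tc, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$truth$genes, paths["truth_genes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGeneSets(dataset$geneSets, paths["gene_sets"])
  invisible(paths)
}

#' Read back a fixture directory written by \code{writeFixture}
#'
#' @param dir fixture directory
#' @return list with \code{meth}, \code{expr}, \code{design},
#'   \code{annotation}, \code{truth}, \code{geneSets}
#' @export
readFixture <- function(dir) {
  beta <- readArrayMatrix(file.path(dir, "beta.tsv"), "beta")
  detp <- readArrayMatrix(file.path(dir, "detection_p.tsv"), "detection_p")
  exprs <- readArrayMatrix(file.path(dir, "expression.tsv"), "expression")
  annot <- readCpGAnnotation(file.path(dir, "annotation.tsv"))
  design <- readSampleDesign(file.path(dir, "design.tsv"))
  truthC <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                              sep = "\t", quote = "", stringsAsFactors = FALSE,
                              na.strings = NULL,
                              colClasses = c(region = "character",
                                             gene = "character",
                                             chromosome = "character"))
  truthG <- NULL
  if (file.exists(file.path(dir, "truth_genes.tsv")))
    truthG <- utils::read.table(file.path(dir, "truth_genes.tsv"),
                                header = TRUE, sep = "\t", quote = "",
                                stringsAsFactors = FALSE)
  sets <- if (file.exists(file.path(dir, "gene_sets.gmt")))
    readGeneSets(file.path(dir, "gene_sets.gmt")) else NULL
  list(meth = MethylExperiment(beta, design, detectionP = detp,
                               annotation = annot),
       expr = ExprExperiment(exprs, design),
       design = design, annotation = annot,
       truth = list(cpgs = truthC, genes = truthG), geneSets = sets)
}
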