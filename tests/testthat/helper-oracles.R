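# Independent brute-force oracles and fixture builders. These deliberately
# re-derive each quantity from its definition, without reusing package code
# paths.

# Benjamini-Hochberg by definition: q_i = min over sorted positions j with
# p_(j) >= p_i of m * p_(j) / j, capped at 1.
bruteBH <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    j <- which(ps >= pi)
    min(1, min(m * ps[j] / j))
  }, numeric(1))
}

# Closed-form Pearson chi-square for a 2x2 table.
bruteChi2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Prediction probability by explicit record scan.
brutePredProb <- function(records, direction, cut, region, folds = c(2, 5),
                          qCut = 0.05, requireExprQ = TRUE) {
  qualSet <- character(0)
  hitSet <- stats::setNames(vector("list", length(folds)), as.character(folds))
  for (k in seq_along(folds)) hitSet[[k]] <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$region_class != region) next
    if (is.na(r$meth_q) || r$meth_q > qCut) next
    ok <- if (direction == "decrease") r$delta_beta < -cut else
      r$delta_beta > cut
    if (!ok) next
    qualSet <- union(qualSet, r$cpg_id)
    for (k in seq_along(folds)) {
      f <- folds[k]
      eok <- if (direction == "decrease") r$fold_change <= -f else
        r$fold_change >= f
      if (requireExprQ) eok <- eok && !is.na(r$expr_q) && r$expr_q <= qCut
      if (isTRUE(eok)) hitSet[[k]] <- union(hitSet[[k]], r$cpg_id)
    }
  }
  probs <- vapply(hitSet, function(h)
    if (length(qualSet)) length(h) / length(qualSet) else NA_real_,
    numeric(1))
  list(n = length(qualSet), probs = unname(probs))
}

# Category table counts by explicit scan: counts of fetal/adult methylation
# levels per (context, tissue, region class) stratum.
bruteCategoryCounts <- function(records, context, tissue, regionClass,
                                bins = c(0.3, 0.7)) {
  counts <- c(HYPO = 0L, INTERMEDIATE = 0L, HYPER = 0L)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (as.character(r$expr_class) != context) next
    if (r$region_class != regionClass) next
    b <- if (tissue == "fetal") r$mean_fetal else r$mean_adult
    lev <- if (b < bins[1]) "HYPO" else if (b < bins[2]) "INTERMEDIATE" else "HYPER"
    counts[lev] <- counts[lev] + 1L
  }
  counts
}

# Random integration-record fixtures for oracle comparisons.
randomRecords <- function(n, seed) {
  withr::with_seed(seed, {
    mf <- runif(n); ma <- runif(n)
    data.frame(
      cpg_id = sprintf("cg%04d", sample.int(max(2L, n %/% 2L), n, replace = TRUE)),
      gene = sprintf("G%03d", sample.int(max(2L, n %/% 3L), n, replace = TRUE)),
      region_class = sample(c("TSS_EX1", "UTR_GB"), n, replace = TRUE),
      mean_fetal = mf, mean_adult = ma, delta_beta = ma - mf,
      meth_q = runif(n),
      expr_class = factor(sample(c("FETAL_OVER", "ADULT_OVER", "SIMILAR",
                                   "OTHER"), n, replace = TRUE),
                          levels = c("FETAL_OVER", "ADULT_OVER", "SIMILAR",
                                     "OTHER")),
      fold_change = sample(c(-1, 1), n, replace = TRUE) * runif(n, 1, 8),
      expr_q = runif(n),
      stringsAsFactors = FALSE)
  })
}

# Small hand-written manifest-style annotation exercising multi-gene and
# multi-region parsing.
toyAnnotation <- function() {
  data.frame(
    IlmnID = c("cg01", "cg02", "cg03", "cg04", "cg05"),
    CHR = c("1", "chr2", "X", "chrY", "3"),
    MAPINFO = c(1000L, 2000L, 3000L, 4000L, 5000L),
    UCSC_RefGene_Name = c("GENEA", "GENEA;GENEB", "GENEA;GENEA",
                          "GENEC", ""),
    UCSC_RefGene_Group = c("TSS200", "TSS1500;Body", "TSS200;TSS200",
                           "Body", ""),
    Regulatory_Feature_Group = c("Promoter_Associated", "", "", "", ""),
    stringsAsFactors = FALSE)
}

# Tiny two-group design.
toyDesign <- function(spg = 3L) {
  data.frame(sample_id = c(paste0("F", seq_len(spg)), paste0("A", seq_len(spg))),
             group = rep(c("fetal", "adult"), each = spg),
             stringsAsFactors = FALSE)
}

# Small MethylExperiment with explicit beta values (rows recycled).
toyMeth <- function(beta, detp = NULL, annot = NULL) {
  MethylExperiment(beta, toyDesign(ncol(beta) %/% 2L), detectionP = detp,
                   annotation = annot)
}
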