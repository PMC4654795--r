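EXPR_CLASSES <- c("FETAL_OVER", "ADULT_OVER", "SIMILAR", "OTHER")
METH_LEVELS <- c("HYPO", "INTERMEDIATE", "HYPER")

# Integer rounding, half away from zero (display convention for percentages;
# counts are always kept unrounded alongside).
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Categorical methylation level of a beta value
#'
#' Hypomethylation is beta in [0, 0.3), intermediate methylation [0.3, 0.7),
#' hypermethylation [0.7, 1.0]. The bins are half-open (upper bound
#' inclusive only for the last) so the three levels form a total partition
#' of [0, 1].
#'
#' @param beta numeric vector in [0, 1]
#' @param bins two inner bin boundaries (default \code{c(0.3, 0.7)})
#' @return factor with levels HYPO, INTERMEDIATE, HYPER
#' @export
classifyMethLevel <- function(beta, bins = c(0.3, 0.7)) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop("beta values must lie in [0,1]")
  lev <- ifelse(is.na(beta), NA_character_,
                ifelse(beta < bins[1L], "HYPO",
                       ifelse(beta < bins[2L], "INTERMEDIATE", "HYPER")))
  factor(lev, levels = METH_LEVELS)
}

#' Expression class of each gene
#'
#' Overexpression (fetal or adult) is a q-significant fold difference of at
#' least \code{overFold} in the corresponding direction; similarly expressed
#' genes have a non-significant signed ratio strictly inside
#' (-\code{similarFold}, +\code{similarFold}); everything else is OTHER. The
#' four classes partition the gene set.
#'
#' @param exprDiff differential-expression table from
#'   \code{\link{diffExpression}}
#' @param overFold overexpression fold threshold (default 5)
#' @param similarFold similar-expression fold bound (default 1.1)
#' @param qCut FDR cutoff (default 0.05)
#' @return data.frame with \code{gene}, \code{expr_class} (factor),
#'   \code{fold_change}, \code{expr_q}
#' @export
classifyExpression <- function(exprDiff, overFold = 5, similarFold = 1.1,
                               qCut = 0.05) {
  q <- exprDiff$q_value
  r <- exprDiff$fold_change
  cls <- ifelse(q <= qCut & r >= overFold, "FETAL_OVER",
         ifelse(q <= qCut & r <= -overFold, "ADULT_OVER",
         ifelse(q > qCut & abs(r) < similarFold, "SIMILAR", "OTHER")))
  data.frame(gene = exprDiff$gene,
             expr_class = factor(cls, levels = EXPR_CLASSES),
             fold_change = r, expr_q = q,
             stringsAsFactors = FALSE)
}

#' Joined CpG-gene methylation/expression records
#'
#' The unit of the contingency and prediction analyses: one record per
#' (CpG, gene) pair (or per (CpG, gene, fine region) with
#' \code{perFineRegion = TRUE}), carrying the aggregate region class, per-
#' tissue mean betas and methylation levels, delta beta and methylation q,
#' and the linked gene's expression class, signed ratio and q. Pairs whose
#' gene is absent from the expression table are dropped.
#'
#' @param methDiff table from \code{\link{diffMethylation}}
#' @param links link table from \code{\link{buildLinks}}
#' @param exprClass table from \code{\link{classifyExpression}}
#' @param bins methylation-level boundaries (see
#'   \code{\link{classifyMethLevel}})
#' @param perFineRegion keep one record per fine RefGene group instead of
#'   collapsing to the aggregate class (needed for fine-region densities)
#' @return data.frame of integration records
#' @export
integrationRecords <- function(methDiff, links, exprClass, bins = c(0.3, 0.7),
                               perFineRegion = FALSE) {
  if (perFineRegion) {
    pairs <- links[links$region_class != "UNANNOTATED",
                   c("cpg_id", "gene", "region", "region_class")]
  } else {
    pairs <- cpgRegionClass(links)
  }
  i <- match(pairs$cpg_id, methDiff$cpg_id)
  j <- match(pairs$gene, exprClass$gene)
  keep <- !is.na(i) & !is.na(j)
  pairs <- pairs[keep, , drop = FALSE]
  i <- i[keep]; j <- j[keep]
  out <- data.frame(
    pairs,
    mean_fetal = methDiff$mean_fetal[i],
    mean_adult = methDiff$mean_adult[i],
    delta_beta = methDiff$delta_beta[i],
    meth_q = methDiff$q_value[i],
    expr_class = exprClass$expr_class[j],
    fold_change = exprClass$fold_change[j],
    expr_q = exprClass$expr_q[j],
    stringsAsFactors = FALSE)
  out$fetal_level <- classifyMethLevel(out$mean_fetal, bins)
  out$adult_level <- classifyMethLevel(out$mean_adult, bins)
  rownames(out) <- NULL
  out
}

#' Gene-level methylation versus expression table
#'
#' Implements the filtering hierarchy relating average gene methylation to
#' the fetal:adult expression ratio: CpGs qualify by methylation
#' significance (q <= \code{qCut}), optionally by a delta-beta magnitude cut
#' and by aggregate region; each gene with at least one qualifying CpG is
#' reported with the mean fetal and adult beta over its qualifying CpGs and
#' its signed expression ratio. The four canonical filter combinations are
#' (a) significance only, (b) + |delta beta| cut, (c) significance +
#' TSS/Ex1, (d) all three.
#'
#' @param methDiff table from \code{\link{diffMethylation}}
#' @param links link table from \code{\link{buildLinks}}
#' @param exprDiff table from \code{\link{diffExpression}}
#' @param qCut methylation FDR cutoff (default 0.05)
#' @param minAbsDbeta minimum |delta beta| (strict; 0 disables the cut)
#' @param region \code{"TSS_EX1"}, \code{"UTR_GB"} or NULL for all
#' @param directional if not NULL, \code{"decrease"}/\code{"increase"}
#'   requires the signed delta beta beyond the cut instead of the absolute
#'   value
#' @return data.frame with \code{gene}, \code{mean_fetal}, \code{mean_adult},
#'   \code{n_cpgs}, \code{fold_change}
#' @export
relationshipTable <- function(methDiff, links, exprDiff, qCut = 0.05,
                              minAbsDbeta = 0, region = NULL,
                              directional = NULL) {
  pairs <- cpgRegionClass(links)
  if (!is.null(region)) {
    region <- match.arg(region, c("TSS_EX1", "UTR_GB"))
    pairs <- pairs[pairs$region_class == region, , drop = FALSE]
  }
  i <- match(pairs$cpg_id, methDiff$cpg_id)
  keep <- !is.na(i)
  pairs <- pairs[keep, , drop = FALSE]; i <- i[keep]
  db <- methDiff$delta_beta[i]
  qual <- !is.na(methDiff$q_value[i]) & methDiff$q_value[i] <= qCut
  if (minAbsDbeta > 0) {
    dirok <- if (is.null(directional)) abs(db) > minAbsDbeta
    else if (directional == "decrease") db < -minAbsDbeta
    else db > minAbsDbeta
    qual <- qual & dirok
  }
  pairs <- pairs[qual, , drop = FALSE]; i <- i[qual]
  genes <- sort(unique(pairs$gene))
  if (!length(genes))
    return(data.frame(gene = character(), mean_fetal = numeric(),
                      mean_adult = numeric(), n_cpgs = integer(),
                      fold_change = numeric(), stringsAsFactors = FALSE))
  mF <- tapply(methDiff$mean_fetal[i], pairs$gene, mean)[genes]
  mA <- tapply(methDiff$mean_adult[i], pairs$gene, mean)[genes]
  fc <- exprDiff$fold_change[match(genes, exprDiff$gene)]
  data.frame(gene = genes, mean_fetal = as.numeric(mF),
             mean_adult = as.numeric(mA),
             n_cpgs = as.integer(table(pairs$gene)[genes]),
             fold_change = fc, row.names = NULL, stringsAsFactors = FALSE)
}

#' Contingency table of CpG methylation levels by expression context
#'
#' For each expression context (gene class), tissue and aggregate region
#' class, counts the CpG records at each methylation level and reports
#' integer percentages (half-up rounding; raw counts retained). Empty strata
#' are flagged with NA percentages rather than divided.
#'
#' @param records integration records from \code{\link{integrationRecords}}
#' @param contexts expression classes to tabulate (default the three used in
#'   the categorical analysis)
#' @param dedupCpGs count each CpG once per stratum even when linked to
#'   several qualifying genes (default FALSE: one count per (CpG, gene) link)
#' @param bins methylation-level boundaries (see
#'   \code{\link{classifyMethLevel}})
#' @return data.frame with one row per (context, tissue, region_class):
#'   counts \code{n_cpgs}, \code{n_hypo}, \code{n_intermediate},
#'   \code{n_hyper} and percentages \code{pct_hypo}, \code{pct_intermediate},
#'   \code{pct_hyper}
#' @export
categoryTable <- function(records,
                          contexts = c("FETAL_OVER", "ADULT_OVER", "SIMILAR"),
                          dedupCpGs = FALSE, bins = c(0.3, 0.7)) {
  grid <- expand.grid(context = contexts, tissue = GROUP_LEVELS,
                      region_class = c("TSS_EX1", "UTR_GB"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    sub <- records[records$expr_class == g$context &
                     records$region_class == g$region_class, , drop = FALSE]
    if (dedupCpGs) sub <- sub[!duplicated(sub$cpg_id), , drop = FALSE]
    lev <- classifyMethLevel(
      if (g$tissue == "fetal") sub$mean_fetal else sub$mean_adult, bins)
    cnt <- table(lev)
    n <- sum(cnt)
    pct <- if (n > 0) roundHalfUp(100 * as.numeric(cnt) / n) else
      rep(NA_real_, 3L)
    data.frame(g, n_cpgs = n,
               n_hypo = as.integer(cnt["HYPO"]),
               n_intermediate = as.integer(cnt["INTERMEDIATE"]),
               n_hyper = as.integer(cnt["HYPER"]),
               pct_hypo = pct[1L], pct_intermediate = pct[2L],
               pct_hyper = pct[3L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test of a count table
#'
#' Pearson statistic on an r x c table of non-negative counts with
#' df = (r-1)(c-1) and an upper-tail chi-square p-value (no continuity
#' correction). Tables with a zero row or column marginal are rejected
#' (expected counts undefined); a flag marks tables with any expected
#' count below 5, where the chi-square approximation is unreliable.
#'
#' @param counts numeric matrix of counts, at least 2 x 2
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{low_expected} (logical flag)
#' @export
chiSquareTest <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal: expected counts undefined")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), low_expected = any(ht$expected < 5))
}

#' Probability that a methylation change predicts an expression change
#'
#' Among CpGs with a q-significant methylation change in the stated
#' direction (fetal-to-adult decrease: delta beta < -\code{dbetaCut};
#' increase: delta beta > +\code{dbetaCut}) and in the stated aggregate
#' region, the probability that the CpG lies on a gene whose expression
#' changed in the opposite direction by at least each fold cut (decreased
#' methylation predicting adult overexpression, increased methylation
#' predicting fetal overexpression). A CpG linked to several genes qualifies
#' if any linked gene meets the expression criterion. By default the
#' expression change must also be q-significant.
#'
#' @param records integration records (one row per (CpG, gene) pair)
#' @param direction \code{"decrease"} or \code{"increase"} (fetal-to-adult)
#' @param dbetaCut minimum |delta beta| (strict), e.g. 0.2 or 0.5
#' @param region \code{"TSS_EX1"} or \code{"UTR_GB"}
#' @param foldCuts expression fold-change cuts (default \code{c(2, 5)})
#' @param qCut methylation FDR cutoff (default 0.05)
#' @param requireExprQ also require expression q <= \code{qCut}
#'   (default TRUE)
#' @return one-row data.frame: \code{direction}, \code{dbeta_cut},
#'   \code{region_class}, \code{n_cpgs} and one probability column
#'   \code{prob_ge<fold>} per fold cut (NA with a zero-CpG stratum)
#' @export
predictionProbability <- function(records, direction = c("decrease", "increase"),
                                  dbetaCut = 0.2,
                                  region = c("TSS_EX1", "UTR_GB"),
                                  foldCuts = c(2, 5), qCut = 0.05,
                                  requireExprQ = TRUE) {
  direction <- match.arg(direction)
  region <- match.arg(region)
  sub <- records[records$region_class == region &
                   !is.na(records$meth_q) & records$meth_q <= qCut, ,
                 drop = FALSE]
  sub <- if (direction == "decrease")
    sub[sub$delta_beta < -dbetaCut, , drop = FALSE]
  else sub[sub$delta_beta > dbetaCut, , drop = FALSE]
  cpgs <- unique(sub$cpg_id)
  out <- data.frame(direction = direction, dbeta_cut = dbetaCut,
                    region_class = region, n_cpgs = length(cpgs),
                    stringsAsFactors = FALSE)
  for (fc in foldCuts) {
    hit <- if (direction == "decrease") sub$fold_change <= -fc
    else sub$fold_change >= fc
    if (requireExprQ) hit <- hit & !is.na(sub$expr_q) & sub$expr_q <= qCut
    hitCpgs <- unique(sub$cpg_id[hit])
    out[[paste0("prob_ge", fc)]] <-
      if (length(cpgs)) length(hitCpgs) / length(cpgs) else NA_real_
  }
  out
}

#' Binned beta densities stratified by region and expression context
#'
#' Normalized (unit-area) histograms of per-tissue mean beta values for each
#' combination of expression context and region stratum (aggregate class or
#' fine RefGene group). Any significance or delta-beta filtering is applied
#' by the caller before this summary.
#'
#' @param records integration records (use \code{perFineRegion = TRUE}
#'   upstream when stratifying by fine region)
#' @param stratifyBy \code{"region_class"} or \code{"region"}
#' @param contexts expression contexts to include
#' @param binWidth histogram bin width over [0, 1] (default 0.05)
#' @return data.frame with \code{context}, \code{tissue}, \code{stratum},
#'   \code{bin_start}, \code{bin_end}, \code{density}, \code{n}
#' @export
densitySummary <- function(records, stratifyBy = c("region_class", "region"),
                           contexts = c("FETAL_OVER", "ADULT_OVER", "SIMILAR"),
                           binWidth = 0.05) {
  stratifyBy <- match.arg(stratifyBy)
  if (!stratifyBy %in% colnames(records))
    stop("records lack a '", stratifyBy, "' column")
  strata <- unique(records[[stratifyBy]])
  rows <- list()
  for (ctx in contexts) for (st in strata) for (ts in GROUP_LEVELS) {
    sub <- records[records$expr_class == ctx &
                     records[[stratifyBy]] == st, , drop = FALSE]
    v <- if (ts == "fetal") sub$mean_fetal else sub$mean_adult
    v <- v[!is.na(v)]
    h <- betaHistogram(v, binWidth = binWidth)
    dens <- if (length(v)) h$count / (length(v) * binWidth) else
      rep(NA_real_, nrow(h))
    rows[[length(rows) + 1L]] <- data.frame(
      context = ctx, tissue = ts, stratum = st,
      bin_start = h$bin_start, bin_end = h$bin_end,
      density = dens, n = length(v), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
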