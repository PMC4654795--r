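#' Detection p-value quality filter
#'
#' Retains probes whose detection p-value is below the threshold in every
#' sample (the strictest reading of array quality filtering); a missing
#' detection p-value counts as a failure. The number of removed probes is
#' recorded in \code{metadata(x)$n_removed_detection}.
#'
#' @param x a \linkS4class{MethylExperiment} carrying a \code{detectionP} assay
#' @param threshold detection p-value cutoff (default 0.05)
#' @return the filtered \code{MethylExperiment}
#' @export
filterDetection <- function(x, threshold = 0.05) {
  dp <- detectionP(x)
  if (is.null(dp))
    stop("no 'detectionP' assay present")
  if (!identical(dim(dp), dim(betaValues(x))))
    stop("detection p-value matrix shape does not match beta matrix")
  keep <- if (nrow(dp)) rowSums(!is.na(dp) & dp < threshold) == ncol(dp) else logical(0)
  out <- x[keep, ]
  metadata(out)$n_removed_detection <- sum(!keep)
  out
}

#' Remove probes on the sex chromosomes
#'
#' Drops probes annotated to chromosome X or Y. Chromosome labels are
#' normalized by stripping an optional \code{chr} prefix, so \code{"X"} and
#' \code{"chrX"} are both removed. Probes lacking a chromosome annotation
#' raise an error listing the offending ids.
#'
#' @param x a \linkS4class{MethylExperiment} whose \code{rowData} carries a
#'   \code{CHR} column
#' @return the filtered \code{MethylExperiment}; removed count in
#'   \code{metadata(x)$n_removed_sex}
#' @export
filterSexChromosomes <- function(x) {
  rd <- rowData(x)
  if (!"CHR" %in% colnames(rd))
    stop("no chromosome annotation ('CHR') in rowData")
  chr <- as.character(rd$CHR)
  miss <- is.na(chr) | chr == ""
  if (any(miss))
    stop("probe(s) missing chromosome annotation: ",
         paste(utils::head(rownames(x)[miss], 5L), collapse = ", "))
  sex <- toupper(normalizeChromosome(chr)) %in% c("X", "Y")
  out <- x[!sex, ]
  metadata(out)$n_removed_sex <- sum(sex)
  out
}

#' Logit (M-value) transform of beta values
#'
#' Computes \eqn{M = \log_2((\beta + o) / (1 - \beta + o))} with a small
#' offset \eqn{o} that keeps the transform finite at beta = 0 and 1. Testing
#' is performed on this scale while effect sizes are reported on the beta
#' scale.
#'
#' @param beta numeric matrix or vector of beta values in [0, 1] (NA allowed)
#' @param offset small positive proportion added to numerator and denominator
#'   (default \code{1e-6}); \code{0} is allowed if no beta touches 0 or 1
#' @return M-values with the shape of \code{beta}
#' @export
logitTransform <- function(beta, offset = 1e-6) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop("beta values must lie in [0,1]")
  if (offset < 0) stop("offset must be non-negative")
  log2((beta + offset) / (1 - beta + offset))
}

#' @rdname logitTransform
#' @param x a \linkS4class{MethylExperiment}
#' @export
mValues <- function(x, offset = 1e-6) logitTransform(betaValues(x), offset)

#' Per-feature two-group linear model
#'
#' Fits, per feature (row), an ordinary least-squares model of the value on
#' the group indicator plus any numeric covariates in the design. The
#' reported effect is the adult-minus-fetal coefficient. For the plain
#' two-group design missing values are excluded pairwise (per-feature
#' complete observations); designs with covariates require complete data.
#'
#' @param m numeric feature-by-sample matrix (M-values or log2 expression)
#' @param design design data.frame with \code{sample_id}, \code{group} and
#'   optional numeric covariate columns, covering all columns of \code{m}
#' @return data.frame with one row per feature: \code{effect} (adult - fetal),
#'   \code{s2} (residual variance), \code{df} (residual degrees of freedom),
#'   \code{leverage} (unscaled variance of the effect, i.e. the diagonal
#'   element of \eqn{(X'X)^{-1}} for the group coefficient)
#' @export
fitGroupModel <- function(m, design) {
  if (is.vector(m)) m <- matrix(m, nrow = 1L, dimnames = list("feature", names(m)))
  design <- .validateDesign(design, colnames(m))
  m <- m[, design$sample_id, drop = FALSE]
  covars <- setdiff(colnames(design), c("sample_id", "group"))
  g <- design$group
  if (length(covars) == 0L) {
    isF <- g == "fetal"; isA <- g == "adult"
    nF <- rowSums(!is.na(m[, isF, drop = FALSE]))
    nA <- rowSums(!is.na(m[, isA, drop = FALSE]))
    mF <- rowMeans(m[, isF, drop = FALSE], na.rm = TRUE)
    mA <- rowMeans(m[, isA, drop = FALSE], na.rm = TRUE)
    ssF <- rowSums((m[, isF, drop = FALSE] - mF)^2, na.rm = TRUE)
    ssA <- rowSums((m[, isA, drop = FALSE] - mA)^2, na.rm = TRUE)
    df <- nF + nA - 2L
    s2 <- ifelse(df > 0, (ssF + ssA) / pmax(df, 1L), NA_real_)
    out <- data.frame(effect = mA - mF, s2 = s2, df = df,
                      leverage = 1 / nF + 1 / nA, row.names = rownames(m))
  } else {
    X <- stats::model.matrix(~ group + .,
                             data = design[, c("group", covars), drop = FALSE])
    if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
    if (anyNA(m)) stop("missing values are not supported with covariates")
    qrX <- qr(X)
    coefs <- t(qr.coef(qrX, t(m)))
    resid <- m - coefs %*% t(X)
    df <- nrow(X) - ncol(X)
    if (df < 1L) stop("no residual degrees of freedom")
    lev <- chol2inv(qr.R(qrX))["groupadult" == colnames(X),
                               "groupadult" == colnames(X)]
    out <- data.frame(effect = coefs[, "groupadult"],
                      s2 = rowSums(resid^2) / df, df = df,
                      leverage = lev, row.names = rownames(m))
  }
  out$zero_variance <- !is.na(out$s2) & out$s2 == 0
  out
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on the monotone
# decreasing trigamma function; asymptotic starts for extreme x.
trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NaN)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in seq_len(60L)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Models the per-feature sample variances as draws from a scaled
#' F-distribution around a common prior variance \eqn{s_0^2} with prior
#' degrees of freedom \eqn{d_0}, estimated by method of moments on the log
#' variances (digamma/trigamma matching). Each feature's posterior variance
#' is the precision-weighted compromise
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d\, s^2) / (d_0 + d).}
#' When the observed log-variances spread no more than sampling noise
#' predicts, \eqn{d_0} is infinite and every posterior equals the common
#' variance. Zero-variance features are excluded from estimation and assigned
#' the prior variance.
#'
#' @param s2 per-feature sample variances
#' @param df residual degrees of freedom (scalar or per-feature)
#' @return a \code{ModerationEstimate}: list with \code{d0}, \code{s20},
#'   \code{posterior} (per-feature) and the input \code{df}
#' @export
moderateVariances <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L)
    stop("need at least 2 features with positive variance and df > 0")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigammaInverse(evar)
    s20 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond sampling noise: infinite prior df; the common
    # variance is the geometric mean of the observed variances
    d0 <- Inf
    s20 <- exp(mean(z))
  }
  posterior <- posteriorVariance(s2, df, d0, s20)
  posterior[!ok] <- s20
  structure(list(d0 = d0, s20 = s20, posterior = posterior, df = df),
            class = "ModerationEstimate")
}

#' @rdname moderateVariances
#' @param d0 prior degrees of freedom (0 = no moderation, Inf = full shrinkage)
#' @param s20 prior variance
#' @export
posteriorVariance <- function(s2, df, d0, s20) {
  if (is.infinite(d0)) return(rep_len(s20, length(s2)))
  if (d0 == 0) return(s2)
  (d0 * s20 + df * s2) / (d0 + df)
}

#' @export
print.ModerationEstimate <- function(x, ...) {
  cat(sprintf("ModerationEstimate: d0 = %s, s0^2 = %.6g, %d features\n",
              format(x$d0, digits = 4), x$s20, length(x$posterior)))
  invisible(x)
}

#' Moderated t-test from a fitted group model
#'
#' Computes \eqn{t = \mathrm{effect} / \sqrt{\tilde s^2 \cdot \mathrm{leverage}}}
#' and a two-sided p-value from the t-distribution with \eqn{d + d_0} degrees
#' of freedom. With \code{d0 = 0} this is the ordinary two-sample
#' (or covariate-adjusted) t-test; with infinite \code{d0} the reference
#' distribution is normal.
#'
#' @param fit data.frame from \code{\link{fitGroupModel}}
#' @param moderation a \code{ModerationEstimate} from
#'   \code{\link{moderateVariances}}, or NULL for the unmoderated test
#' @return data.frame with per-feature \code{t}, \code{p_value},
#'   \code{df_total}, \code{posterior_var}
#' @export
moderatedTest <- function(fit, moderation = NULL) {
  if (is.null(moderation)) {
    post <- fit$s2
    d0 <- 0
  } else {
    post <- moderation$posterior
    d0 <- moderation$d0
  }
  se <- sqrt(post * fit$leverage)
  t <- fit$effect / se
  dfT <- fit$df + d0
  p <- 2 * stats::pt(-abs(t), df = dfT)
  p[is.na(t)] <- NA_real_
  data.frame(t = t, p_value = p, df_total = dfT, posterior_var = post,
             row.names = rownames(fit))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j},
#' capped at 1. Delegates to \code{stats::p.adjust} after validating the
#' input range.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed and propagated)
#' @return q-values, same length and order as \code{p}
#' @export
bhFDR <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Signed expression fold change
#'
#' Converts log2 group means into the signed-ratio convention: +r when the
#' fetal mean is at least the adult mean (r = fetal/adult fold), -r when the
#' adult mean is higher. The magnitude is always >= 1 and equal means give +1.
#'
#' @param fetal,adult log2 group mean expression (vectors)
#' @return signed fold changes
#' @export
signedFoldChange <- function(fetal, adult) {
  r <- 2^(fetal - adult)
  ifelse(r >= 1, r, -1 / r)
}

#' Per-group variance summary of a beta matrix
#'
#' Per-CpG sample variances (n - 1 denominator, pairwise-complete) within
#' each group, summarized as the group mean variance and the fraction of
#' CpGs below a cutoff.
#'
#' @param x a \linkS4class{MethylExperiment}
#' @param cutoff variance cutoff for the reported fraction (default 0.01)
#' @return data.frame with one row per group: \code{group},
#'   \code{mean_variance}, \code{fraction_below}, \code{cutoff}
#' @export
varianceSummary <- function(x, cutoff = 0.01) {
  b <- betaValues(x)
  g <- sampleGroups(x)
  do.call(rbind, lapply(GROUP_LEVELS, function(lv) {
    sub <- b[, g == lv, drop = FALSE]
    v <- rowVarsNA(sub)
    data.frame(group = lv, mean_variance = mean(v, na.rm = TRUE),
               fraction_below = mean(v < cutoff, na.rm = TRUE),
               cutoff = cutoff, stringsAsFactors = FALSE)
  }))
}

# Row variances with pairwise NA exclusion, n-1 denominator.
rowVarsNA <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  ifelse(n > 1, ss / (n - 1), NA_real_)
}

#' Fixed-width histogram of beta or delta-beta values
#'
#' Bins are left-closed, right-open, with the final bin closed on both
#' sides, over a declared range (default [0, 1], width 0.05, i.e. 20 bins).
#' Values outside the range raise an error.
#'
#' @param values numeric vector
#' @param binWidth bin width (default 0.05)
#' @param range two-element numeric range (default \code{c(0, 1)})
#' @return data.frame with \code{bin_start}, \code{bin_end}, \code{count}
#' @export
betaHistogram <- function(values, binWidth = 0.05, range = c(0, 1)) {
  values <- values[!is.na(values)]
  if (any(values < range[1L] | values > range[2L]))
    stop(sprintf("value(s) outside declared range [%g, %g]: first offender %g",
                 range[1L], range[2L],
                 values[which(values < range[1L] | values > range[2L])[1L]]))
  nb <- ceiling((range[2L] - range[1L]) / binWidth - 1e-9)
  starts <- range[1L] + (seq_len(nb) - 1L) * binWidth
  ends <- pmin(starts + binWidth, range[2L])
  idx <- pmin(floor((values - range[1L]) / binWidth) + 1L, nb)
  data.frame(bin_start = starts, bin_end = ends,
             count = tabulate(idx, nbins = nb))
}

#' Differential methylation analysis
#'
#' Runs the moderated two-group comparison on M-values (logit-transformed
#' betas) and reports effects on the beta scale: per-CpG group mean betas,
#' delta beta (adult minus fetal), per-group beta variances, moderated t,
#' raw p and BH q. Set \code{moderate = FALSE} for the ordinary t-test.
#'
#' @param x a filtered \linkS4class{MethylExperiment}
#' @param offset logit offset (see \code{\link{logitTransform}})
#' @param moderate apply empirical-Bayes variance moderation (default TRUE)
#' @return data.frame (one row per CpG): \code{cpg_id}, \code{mean_fetal},
#'   \code{mean_adult}, \code{delta_beta}, \code{var_fetal}, \code{var_adult},
#'   \code{t}, \code{p_value}, \code{q_value}; the moderation estimate is
#'   attached as attribute \code{"moderation"}
#' @export
diffMethylation <- function(x, offset = 1e-6, moderate = TRUE) {
  design <- data.frame(sample_id = colnames(x), group = sampleGroups(x))
  m <- mValues(x, offset)
  fit <- fitGroupModel(m, design)
  mod <- if (moderate) moderateVariances(fit$s2, fit$df) else NULL
  tst <- moderatedTest(fit, mod)
  b <- betaValues(x)
  g <- sampleGroups(x)
  bF <- b[, g == "fetal", drop = FALSE]
  bA <- b[, g == "adult", drop = FALSE]
  mF <- rowMeans(bF, na.rm = TRUE)
  mA <- rowMeans(bA, na.rm = TRUE)
  out <- data.frame(cpg_id = rownames(x), mean_fetal = mF, mean_adult = mA,
                    delta_beta = mA - mF,
                    var_fetal = rowVarsNA(bF), var_adult = rowVarsNA(bA),
                    t = tst$t, p_value = tst$p_value,
                    q_value = bhFDR(tst$p_value),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "moderation") <- mod
  out
}

#' Differential expression analysis
#'
#' Moderated two-group comparison of log2 expression. The reported effect is
#' the fetal-minus-adult log2 ratio together with the signed fold change
#' (+r = fetal higher, -r = adult higher, |r| >= 1).
#'
#' @param x an \linkS4class{ExprExperiment}
#' @param moderate apply empirical-Bayes variance moderation (default TRUE)
#' @return data.frame (one row per gene): \code{gene}, \code{mean_fetal},
#'   \code{mean_adult}, \code{log2_ratio}, \code{fold_change},
#'   \code{var_fetal}, \code{var_adult}, \code{t}, \code{p_value},
#'   \code{q_value}; moderation estimate attached as attribute
#'   \code{"moderation"}
#' @export
diffExpression <- function(x, moderate = TRUE) {
  design <- data.frame(sample_id = colnames(x), group = sampleGroups(x))
  e <- assay(x, "exprs")
  fit <- fitGroupModel(e, design)
  mod <- if (moderate) moderateVariances(fit$s2, fit$df) else NULL
  tst <- moderatedTest(fit, mod)
  g <- sampleGroups(x)
  eF <- e[, g == "fetal", drop = FALSE]
  eA <- e[, g == "adult", drop = FALSE]
  mF <- rowMeans(eF); mA <- rowMeans(eA)
  out <- data.frame(gene = rownames(x), mean_fetal = mF, mean_adult = mA,
                    log2_ratio = mF - mA,
                    fold_change = signedFoldChange(mF, mA),
                    var_fetal = rowVarsNA(eF), var_adult = rowVarsNA(eA),
                    t = -tst$t, p_value = tst$p_value,
                    q_value = bhFDR(tst$p_value),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "moderation") <- mod
  out
}
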