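#' @importFrom jsonlite write_json
NULL

#' Pipeline configuration
#'
#' Collects every tunable threshold of the end-to-end analysis with the
#' canonical defaults: detection p < 0.05 in all samples, FDR q <= 0.05,
#' delta-beta cuts 0.2 and 0.5, 5-fold overexpression, 1.1-fold similarity
#' bound, 2- and 5-fold prediction cuts, methylation-level bins at 0.3 and
#' 0.7, 0.05 histogram bins, logit offset 1e-6 and 5 control gene sets.
#'
#' @param inputDir directory holding beta.tsv, detection_p.tsv,
#'   expression.tsv, annotation.tsv, design.tsv (and optionally
#'   gene_sets.gmt), as written by \code{\link{writeFixture}}; may be NULL
#'   when an in-memory dataset is passed to \code{\link{runPipeline}}
#' @param outputDir directory for stage outputs and the run manifest
#' @param detectionThreshold,qCut,dbetaCuts,overFold,similarFold,foldCuts
#'   analysis thresholds (defaults above)
#' @param methBins,histWidth,logitOffset,kControls further defaults
#' @param requireExprQ require expression q-significance in the prediction
#'   probabilities (default TRUE)
#' @param seed RNG seed for the control-set stage
#' @return a \code{PipelineConfig} (validated list)
#' @export
pipelineConfig <- function(inputDir = NULL, outputDir,
                           detectionThreshold = 0.05, qCut = 0.05,
                           dbetaCuts = c(0.2, 0.5), overFold = 5,
                           similarFold = 1.1, foldCuts = c(2, 5),
                           methBins = c(0.3, 0.7), histWidth = 0.05,
                           logitOffset = 1e-6, kControls = 5,
                           requireExprQ = TRUE, seed = 1L) {
  stopifnot(detectionThreshold > 0, detectionThreshold <= 1,
            qCut > 0, qCut <= 1, all(dbetaCuts > 0), all(dbetaCuts <= 1),
            overFold >= 1, similarFold >= 1, all(foldCuts >= 1),
            length(methBins) == 2L, all(methBins > 0), all(methBins < 1),
            methBins[1L] < methBins[2L], histWidth > 0, histWidth <= 1,
            logitOffset >= 0, kControls >= 1)
  structure(list(inputDir = inputDir, outputDir = outputDir,
                 detectionThreshold = detectionThreshold, qCut = qCut,
                 dbetaCuts = dbetaCuts, overFold = overFold,
                 similarFold = similarFold, foldCuts = foldCuts,
                 methBins = methBins, histWidth = histWidth,
                 logitOffset = logitOffset, kControls = kControls,
                 requireExprQ = requireExprQ, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.writeTSV <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full methylation-expression integration pipeline
#'
#' Executes six stages in order -- filter (detection p and sex chromosomes),
#' transform (M-values), difftest (differential methylation and expression),
#' regions (CpG-gene links and per-gene means), integrate (relationship
#' tables, category/chi-square, prediction probabilities, densities) and
#' enrich (control-calibrated over-representation) -- writing each stage's
#' TSV outputs plus a machine-readable JSON run manifest (package and R
#' versions, seed, thresholds, input checksums, per-stage record counts) to
#' \code{outputDir}. A stage failure aborts with the stage named; the
#' manifest is still written with a FAILED marker. Identical config and
#' seed reproduce every output byte for byte.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param dataset optional in-memory dataset (as from
#'   \code{\link{simulateDataset}}); when NULL, inputs are read from
#'   \code{config$inputDir}
#' @param verbose log stage progress to stderr (default TRUE)
#' @return invisibly, the report bundle: a list with the filtered
#'   experiment, dm/de tables, links, records, relationship tables,
#'   category table and chi-square tests, prediction rows, density
#'   summaries, enrichment results, counts and the manifest
#' @export
runPipeline <- function(config, dataset = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outputDir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log <- function(...) if (verbose) message("[methexpress] ", ...)
  stages <- list()
  bundle <- list(config = config)
  checksums <- list()
  note <- function(name, n) stages[[length(stages) + 1L]] <<-
    list(name = name, status = "completed", n_records = n)
  fail <- function(name, e) {
    stages[[length(stages) + 1L]] <<-
      list(name = name, status = "FAILED", error = conditionMessage(e))
    .writeManifest(config, stages, checksums, out)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run <- function(name, expr) tryCatch(expr, error = function(e) fail(name, e))

  # --- load inputs ----------------------------------------------------------
  run("load", {
    if (is.null(dataset)) {
      files <- sort(list.files(config$inputDir, full.names = TRUE))
      checksums <- as.list(unname(tools::md5sum(files)))
      names(checksums) <- basename(files)
      dataset <- readFixture(config$inputDir)
    }
    bundle$dataset <- dataset
  })
  dataset <- bundle$dataset

  # --- stage 1: filter ------------------------------------------------------
  run("filter", {
    m <- filterDetection(dataset$meth, config$detectionThreshold)
    nDet <- metadata(m)$n_removed_detection
    m <- filterSexChromosomes(m)
    nSex <- metadata(m)$n_removed_sex
    log(sprintf("filter: removed %d (detection) + %d (sex chrom), %d retained",
                nDet, nSex, nrow(m)))
    bundle$meth <- m
    bundle$counts <- list(n_probes_input = nrow(dataset$meth),
                          n_removed_detection = nDet, n_removed_sex = nSex,
                          n_probes_filtered = nrow(m))
    note("filter", nrow(m))
  })

  # --- stage 2: transform ---------------------------------------------------
  run("transform", {
    mv <- mValues(bundle$meth, config$logitOffset)
    writeArrayMatrix(mv, file.path(out, "mvalues.tsv"))
    note("transform", nrow(mv))
  })

  # --- stage 3: differential tests ------------------------------------------
  run("difftest", {
    dm <- diffMethylation(bundle$meth, offset = config$logitOffset)
    de <- diffExpression(dataset$expr)
    .writeTSV(dm, file.path(out, "dm.tsv"))
    .writeTSV(de, file.path(out, "de.tsv"))
    bundle$dm <- dm; bundle$de <- de
    bundle$varianceSummary <- varianceSummary(bundle$meth)
    .writeTSV(bundle$varianceSummary, file.path(out, "variance_summary.tsv"))
    note("difftest", nrow(dm) + nrow(de))
  })

  # --- stage 4: regions -----------------------------------------------------
  run("regions", {
    links <- buildLinks(cpgAnnotation(bundle$meth))
    .writeTSV(links, file.path(out, "links.tsv"))
    gm <- geneMeanMethylation(bundle$meth, links)
    .writeTSV(gm, file.path(out, "gene_mean_methylation.tsv"))
    bundle$links <- links
    bundle$coverage <- annotationCoverage(dataset$annotation)
    note("regions", nrow(links))
  })

  # --- stage 5: integrate ---------------------------------------------------
  run("integrate", {
    cls <- classifyExpression(bundle$de, config$overFold, config$similarFold,
                              config$qCut)
    rec <- integrationRecords(bundle$dm, bundle$links, cls,
                              bins = config$methBins)
    .writeTSV(rec, file.path(out, "integration_records.tsv"))
    panels <- list(
      a = relationshipTable(bundle$dm, bundle$links, bundle$de,
                            qCut = config$qCut),
      b = relationshipTable(bundle$dm, bundle$links, bundle$de,
                            qCut = config$qCut,
                            minAbsDbeta = config$dbetaCuts[1L]),
      c = relationshipTable(bundle$dm, bundle$links, bundle$de,
                            qCut = config$qCut, region = "TSS_EX1"),
      d = relationshipTable(bundle$dm, bundle$links, bundle$de,
                            qCut = config$qCut,
                            minAbsDbeta = config$dbetaCuts[1L],
                            region = "TSS_EX1"))
    for (p in names(panels))
      .writeTSV(panels[[p]], file.path(out, paste0("relationship_", p, ".tsv")))
    catTab <- categoryTable(rec)
    .writeTSV(catTab, file.path(out, "category_table.tsv"))
    chis <- .categoryChiSquares(catTab)
    .writeTSV(chis, file.path(out, "chi_square.tsv"))
    preds <- do.call(rbind, lapply(c("decrease", "increase"), function(dir)
      do.call(rbind, lapply(config$dbetaCuts, function(cut)
        do.call(rbind, lapply(c("TSS_EX1", "UTR_GB"), function(rg)
          predictionProbability(rec, dir, cut, rg, config$foldCuts,
                                config$qCut, config$requireExprQ)))))))
    .writeTSV(preds, file.path(out, "prediction_probability.tsv"))
    recFine <- integrationRecords(bundle$dm, bundle$links, cls,
                                  bins = config$methBins,
                                  perFineRegion = TRUE)
    sig <- recFine[!is.na(recFine$meth_q) & recFine$meth_q <= config$qCut &
                     abs(recFine$delta_beta) > config$dbetaCuts[1L], ]
    dens <- densitySummary(sig, stratifyBy = "region",
                           binWidth = config$histWidth)
    .writeTSV(dens, file.path(out, "density_summary.tsv"))
    bundle$exprClass <- cls; bundle$records <- rec
    bundle$relationship <- panels; bundle$categoryTable <- catTab
    bundle$chiSquare <- chis; bundle$predictions <- preds
    bundle$densities <- dens
    note("integrate", nrow(rec))
  })

  # --- stage 6: enrich ------------------------------------------------------
  run("enrich", {
    sets <- dataset$geneSets
    enr <- NULL
    if (!is.null(sets)) {
      tss <- bundle$records[bundle$records$region_class == "TSS_EX1" &
                              !is.na(bundle$records$meth_q) &
                              bundle$records$meth_q <= config$qCut &
                              abs(bundle$records$delta_beta) >
                                config$dbetaCuts[1L], ]
      query <- unique(tss$gene[tss$expr_class %in%
                                 c("FETAL_OVER", "ADULT_OVER")])
      pool <- bundle$exprClass$gene[bundle$exprClass$expr_class == "SIMILAR"]
      universe <- bundle$exprClass$gene
      if (length(query) >= 1L &&
          length(setdiff(pool, query)) >= config$kControls * length(query)) {
        enr <- controlCalibratedEnrichment(query, sets, pool, universe,
                                           config$kControls, config$seed)
        .writeTSV(enr$results, file.path(out, "enrichment.tsv"))
      } else {
        log("enrich: query empty or similar pool too small; no scores emitted")
      }
    }
    bundle$enrichment <- enr
    note("enrich", if (is.null(enr)) 0L else nrow(enr$results))
  })

  manifest <- .writeManifest(config, stages, checksums, out)
  bundle$manifest <- manifest
  invisible(bundle)
}

# Chi-square comparisons backing the category table: each overexpressed
# context against the similarly-expressed control, per tissue and region
# class, on the 2 x 3 level-count table.
.categoryChiSquares <- function(cat) {
  combos <- expand.grid(context = c("FETAL_OVER", "ADULT_OVER"),
                        tissue = GROUP_LEVELS,
                        region_class = c("TSS_EX1", "UTR_GB"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    g <- combos[k, ]
    pick <- function(ctx) {
      r <- cat[cat$context == ctx & cat$tissue == g$tissue &
                 cat$region_class == g$region_class, ]
      c(r$n_hypo, r$n_intermediate, r$n_hyper)
    }
    tab <- rbind(pick(g$context), pick("SIMILAR"))
    res <- tryCatch(chiSquareTest(tab), error = function(e) NULL)
    data.frame(g, statistic = if (is.null(res)) NA_real_ else res$statistic,
               df = if (is.null(res)) NA_integer_ else res$df,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               low_expected = if (is.null(res)) NA else res$low_expected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.writeManifest <- function(config, stages, checksums, out) {
  manifest <- list(
    package = "methexpress",
    package_version = as.character(utils::packageVersion("methexpress")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = config[setdiff(names(config), c("inputDir", "outputDir"))],
    input_checksums = checksums,
    stages = stages)
  write_json(manifest, file.path(out, "manifest.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  manifest
}

#' Headline summary of a pipeline run
#'
#' Recomputes the headline statistics of the analysis from a report bundle:
#' probe counts through filtering, the number and percentage of
#' q-significant CpGs, the split of significant CpGs by |delta beta| (<= 0.2
#' and > 0.5), the fraction of small-delta significant CpGs with higher
#' adult methylation, and differential-expression gene counts overall and
#' at the overexpression fold by direction. Percentages over an empty
#' denominator are NA, never 0.
#'
#' @param bundle report bundle from \code{\link{runPipeline}}
#' @return named list of counts and percentages
#' @export
summarizeCounts <- function(bundle) {
  cfg <- bundle$config
  dm <- bundle$dm; de <- bundle$de
  sig <- !is.na(dm$q_value) & dm$q_value <= cfg$qCut
  nSig <- sum(sig)
  small <- sig & abs(dm$delta_beta) <= cfg$dbetaCuts[1L]
  large <- sig & abs(dm$delta_beta) > cfg$dbetaCuts[2L]
  deSig <- !is.na(de$q_value) & de$q_value <= cfg$qCut
  over <- deSig & abs(de$fold_change) >= cfg$overFold
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(bundle$counts,
    list(
      n_significant_cpgs = nSig,
      pct_significant = pct(nSig, nrow(dm)),
      n_sig_small_dbeta = sum(small),
      pct_sig_small_dbeta = pct(sum(small), nSig),
      n_sig_large_dbeta = sum(large),
      pct_adult_higher_small = pct(sum(small & dm$delta_beta > 0), sum(small)),
      n_de_genes = sum(deSig),
      n_over_fold_genes = sum(over),
      n_fetal_over = sum(over & de$fold_change > 0),
      n_adult_over = sum(over & de$fold_change < 0)))
}
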