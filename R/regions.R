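#' Gene-region aggregate classes
#'
#' CpG probes are assigned, per linked gene, to one of two aggregate
#' region classes: \code{TSS_EX1} for sites within 200 or 1,500 bp of the
#' transcription start site or within the first exon (RefGene groups TSS200,
#' TSS1500, 1stExon), and \code{UTR_GB} for the remaining annotated groups
#' (5'UTR, Body, 3'UTR). Probes with no gene annotation are
#' \code{UNANNOTATED}.
#'
#' @param fineRegion character vector of RefGene group labels
#' @return character vector of region classes
#' @export
regionClassOf <- function(fineRegion) {
  out <- ifelse(fineRegion %in% TSS_EX1_GROUPS, "TSS_EX1",
                ifelse(fineRegion %in% REFGENE_GROUPS, "UTR_GB", NA_character_))
  if (anyNA(out))
    stop("unknown RefGene group label(s): ",
         paste(unique(fineRegion[is.na(out)]), collapse = ", "))
  out
}

#' Build the CpG-to-gene link table
#'
#' Expands the semicolon-separated parallel gene/RefGene-group lists of a
#' manifest-style annotation into one row per distinct (CpG, gene, fine
#' region) triple, attaching the aggregate region class. Probes with an
#' empty gene list yield a single UNANNOTATED link with gene NA.
#'
#' @param annot annotation data.frame from \code{\link{readCpGAnnotation}}
#' @return data.frame with columns \code{cpg_id}, \code{gene}, \code{region}
#'   (fine RefGene group) and \code{region_class}
#' @export
buildLinks <- function(annot) {
  genes <- strsplit(annot$UCSC_RefGene_Name, ";", fixed = TRUE)
  groups <- strsplit(annot$UCSC_RefGene_Group, ";", fixed = TRUE)
  genes[annot$UCSC_RefGene_Name == ""] <- list(character(0))
  groups[annot$UCSC_RefGene_Group == ""] <- list(character(0))
  n <- lengths(genes)
  if (any(n != lengths(groups)))
    stop("gene and RefGene-group lists differ in length for probe(s): ",
         paste(annot$IlmnID[n != lengths(groups)], collapse = ", "))
  empty <- n == 0L
  links <- data.frame(
    cpg_id = c(rep.int(annot$IlmnID, n), annot$IlmnID[empty]),
    gene = c(unlist(genes, use.names = FALSE), rep(NA_character_, sum(empty))),
    region = c(unlist(groups, use.names = FALSE), rep(NA_character_, sum(empty))),
    stringsAsFactors = FALSE)
  links <- links[!duplicated(links), , drop = FALSE]
  links$region_class <- "UNANNOTATED"
  ann <- !is.na(links$region)
  links$region_class[ann] <- regionClassOf(links$region[ann])
  rownames(links) <- NULL
  links
}

#' Collapse links to one region class per (CpG, gene) pair
#'
#' A probe annotated to several fine regions of the same gene gets the
#' aggregate class with TSS/Ex1 priority: if any of its links is TSS200,
#' TSS1500 or 1stExon the pair is TSS_EX1, otherwise UTR_GB (promoter-
#' proximal membership dominates).
#'
#' @param links link table from \code{\link{buildLinks}}
#' @return data.frame with one row per (CpG, gene): \code{cpg_id},
#'   \code{gene}, \code{region_class}
#' @export
cpgRegionClass <- function(links) {
  ann <- links[links$region_class != "UNANNOTATED", , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(cpg_id = character(), gene = character(),
                      region_class = character(), stringsAsFactors = FALSE))
  key <- paste(ann$cpg_id, ann$gene, sep = "\r")
  isTss <- ann$region_class == "TSS_EX1"
  anyTss <- tapply(isTss, key, any)
  first <- !duplicated(key)
  out <- data.frame(cpg_id = ann$cpg_id[first], gene = ann$gene[first],
                    stringsAsFactors = FALSE)
  out$region_class <- ifelse(anyTss[key[first]], "TSS_EX1", "UTR_GB")
  rownames(out) <- NULL
  out
}

#' Per-gene mean methylation
#'
#' For each gene, the unweighted mean over its qualifying CpGs of the
#' per-CpG group-mean beta, separately for the fetal and adult groups.
#' Optionally restricted to one aggregate region class (using the TSS/Ex1
#' priority collapse); genes with no qualifying CpG are omitted.
#'
#' @param x a \linkS4class{MethylExperiment}
#' @param links link table from \code{\link{buildLinks}}
#' @param restrict \code{"TSS_EX1"}, \code{"UTR_GB"} or NULL (all annotated
#'   links)
#' @return data.frame with \code{gene}, \code{mean_fetal}, \code{mean_adult},
#'   \code{n_cpgs}
#' @export
geneMeanMethylation <- function(x, links, restrict = NULL) {
  pairs <- cpgRegionClass(links)
  if (!is.null(restrict)) {
    restrict <- match.arg(restrict, c("TSS_EX1", "UTR_GB"))
    pairs <- pairs[pairs$region_class == restrict, , drop = FALSE]
  }
  pairs <- pairs[pairs$cpg_id %in% rownames(x), , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(gene = character(), mean_fetal = numeric(),
                      mean_adult = numeric(), n_cpgs = integer(),
                      stringsAsFactors = FALSE))
  b <- betaValues(x)
  g <- sampleGroups(x)
  mF <- rowMeans(b[, g == "fetal", drop = FALSE], na.rm = TRUE)
  mA <- rowMeans(b[, g == "adult", drop = FALSE], na.rm = TRUE)
  agg <- function(v) tapply(v[pairs$cpg_id], pairs$gene, mean)
  genes <- sort(unique(pairs$gene))
  data.frame(gene = genes,
             mean_fetal = as.numeric(agg(mF)[genes]),
             mean_adult = as.numeric(agg(mA)[genes]),
             n_cpgs = as.integer(table(pairs$gene)[genes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotation coverage summary
#'
#' Counts probes with and without a regulatory-feature-group annotation and
#' with and without a RefGene-group annotation, plus the size of the
#' promoter-associated subset (regulatory feature text containing
#' \code{"Promoter_Associated"}).
#'
#' @param annot annotation data.frame from \code{\link{readCpGAnnotation}}
#' @return list with \code{n_probes}, \code{n_with_regulatory},
#'   \code{n_without_regulatory}, \code{n_with_refgene},
#'   \code{n_without_refgene}, \code{n_promoter_associated} and the two
#'   coverage fractions \code{frac_regulatory}, \code{frac_refgene}
#' @export
annotationCoverage <- function(annot) {
  reg <- !is.na(annot$Regulatory_Feature_Group) &
    annot$Regulatory_Feature_Group != ""
  ref <- !is.na(annot$UCSC_RefGene_Group) & annot$UCSC_RefGene_Group != ""
  prom <- grepl("Promoter_Associated", annot$Regulatory_Feature_Group,
                ignore.case = TRUE)
  n <- nrow(annot)
  list(n_probes = n,
       n_with_regulatory = sum(reg), n_without_regulatory = sum(!reg),
       n_with_refgene = sum(ref), n_without_refgene = sum(!ref),
       n_promoter_associated = sum(prom),
       frac_regulatory = if (n) sum(reg) / n else NA_real_,
       frac_refgene = if (n) sum(ref) / n else NA_real_)
}
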