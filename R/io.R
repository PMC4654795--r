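#' Read a feature-by-sample matrix from TSV
#'
#' Reads a tab-delimited file whose header row holds sample ids and whose
#' first column holds feature ids, and validates it against the declared
#' kind: beta values must lie in [0, 1] (NA allowed), detection p-values in
#' [0, 1], expression values must be finite. Validation errors name the
#' offending row and column.
#'
#' @param path path to a TSV file
#' @param kind one of \code{"beta"}, \code{"detection_p"}, \code{"expression"}
#' @return numeric matrix with feature rownames and sample colnames
#' @export
readArrayMatrix <- function(path, kind = c("beta", "detection_p", "expression")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("matrix file needs a feature-id column plus at least one sample: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated feature id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample id(s) in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (kind %in% c("beta", "detection_p")) {
    bad <- which(!is.na(m) & (m < 0 | m > 1))
    if (length(bad)) {
      i <- arrayInd(bad[1L], dim(m))
      stop(sprintf("%s value out of [0,1] in %s at row '%s', column '%s' (value %g)",
                   kind, path, rownames(m)[i[1L]], colnames(m)[i[2L]], m[bad[1L]]))
    }
  } else if (any(!is.finite(m))) {
    bad <- which(!is.finite(m))
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("non-finite expression value in %s at row '%s', column '%s'",
                 path, rownames(m)[i[1L]], colnames(m)[i[2L]]))
  }
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m numeric matrix with rownames and colnames
#' @param path output file; the feature-id column is written first under
#'   \code{feature_id}
#' @param digits significant digits retained (default keeps full double
#'   precision via \code{format(..., digits = 15)})
#' @export
writeArrayMatrix <- function(m, path, digits = 15L) {
  df <- data.frame(feature_id = rownames(m),
                   format(m, digits = digits, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 450K-manifest-style CpG annotation table
#'
#' Expects tab-delimited columns \code{IlmnID}, \code{CHR}, \code{MAPINFO},
#' \code{UCSC_RefGene_Name}, \code{UCSC_RefGene_Group},
#' \code{Regulatory_Feature_Group}. Gene names and RefGene groups are
#' semicolon-separated parallel lists; empty strings mean unannotated.
#' RefGene groups must come from TSS200, TSS1500, 5'UTR, 1stExon, Body,
#' 3'UTR, and the two lists must have equal length per probe.
#'
#' @param path path to the annotation TSV
#' @return data.frame with the columns above (one row per probe)
#' @export
readCpGAnnotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", na.strings = NULL,
                          colClasses = "character")
  need <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
            "UCSC_RefGene_Group", "Regulatory_Feature_Group")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$IlmnID))
    stop("duplicated probe id(s) in annotation: ",
         paste(unique(df$IlmnID[duplicated(df$IlmnID)]), collapse = ", "))
  df$MAPINFO <- as.integer(df$MAPINFO)
  # validate list structure probe by probe
  genes <- strsplit(df$UCSC_RefGene_Name, ";", fixed = TRUE)
  groups <- strsplit(df$UCSC_RefGene_Group, ";", fixed = TRUE)
  genes[df$UCSC_RefGene_Name == ""] <- list(character(0))
  groups[df$UCSC_RefGene_Group == ""] <- list(character(0))
  ng <- lengths(genes); nr <- lengths(groups)
  bad <- which(ng != nr)
  if (length(bad))
    stop("gene and RefGene-group lists differ in length for probe(s): ",
         paste(df$IlmnID[utils::head(bad, 5L)], collapse = ", "))
  lab <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(unique(lab), REFGENE_GROUPS)
  if (length(unknown))
    stop("unknown RefGene group label(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(REFGENE_GROUPS, collapse = ", "), ")")
  df
}

#' @rdname readCpGAnnotation
#' @param annot annotation data.frame as returned by \code{readCpGAnnotation}
#' @export
writeCpGAnnotation <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Tab-delimited with columns \code{sample_id}, \code{group} (values
#' \code{fetal} or \code{adult}) and optional numeric covariate columns.
#' Each group must contain at least two samples.
#'
#' @param path path to the design TSV
#' @return data.frame with \code{sample_id}, \code{group} (factor) and any
#'   covariates
#' @export
readSampleDesign <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  .validateDesign(df, NULL)
}

#' @rdname readSampleDesign
#' @param design design data.frame
#' @export
writeSampleDesign <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Strip an optional "chr" prefix so manifest ("X") and UCSC ("chrX")
# dialects compare equal; case-insensitive on the prefix.
normalizeChromosome <- function(chr) {
  sub("^[Cc][Hh][Rr]", "", as.character(chr))
}
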