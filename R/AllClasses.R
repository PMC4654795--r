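#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData rowData<- colData
NULL

REFGENE_GROUPS <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")
TSS_EX1_GROUPS <- c("TSS200", "TSS1500", "1stExon")
GROUP_LEVELS <- c("fetal", "adult")

#' Container for array methylation data
#'
#' A \linkS4class{SummarizedExperiment} holding a CpG-by-sample matrix of
#' methylation beta values (assay \code{"beta"}, proportions in [0, 1]) and
#' optionally the matching detection p-value matrix (assay
#' \code{"detectionP"}). Probe annotation (chromosome, position, gene and
#' RefGene-group lists, regulatory feature group) lives in \code{rowData};
#' the sample design (a \code{group} factor with levels \code{fetal} and
#' \code{adult}, plus optional numeric covariates) lives in \code{colData}.
#'
#' @seealso \code{\link{MethylExperiment}} for the constructor,
#'   \code{\link{betaValues}}, \code{\link{detectionP}},
#'   \code{\link{sampleGroups}}
#' @export
setClass("MethylExperiment", contains = "SummarizedExperiment")

#' Container for log2 expression data
#'
#' A \linkS4class{SummarizedExperiment} holding a gene-by-sample matrix of
#' normalized log2 expression values (assay \code{"exprs"}); rows are unique
#' gene symbols. The sample design lives in \code{colData} as for
#' \linkS4class{MethylExperiment}.
#'
#' @seealso \code{\link{ExprExperiment}} for the constructor
#' @export
setClass("ExprExperiment", contains = "SummarizedExperiment")

.checkDesignFrame <- function(cd) {
  if (!"group" %in% colnames(cd))
    return("colData must contain a 'group' column")
  g <- as.character(cd$group)
  bad <- setdiff(unique(g), GROUP_LEVELS)
  if (length(bad))
    return(paste0("unknown group label(s): ", paste(bad, collapse = ", "),
                  " (allowed: ", paste(GROUP_LEVELS, collapse = ", "), ")"))
  NULL
}

setValidity("MethylExperiment", function(object) {
  msg <- character()
  if (!"beta" %in% assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    bad <- which(!is.na(b) & (b < 0 | b > 1))
    if (length(bad)) {
      i <- arrayInd(bad[1L], dim(b))
      msg <- c(msg, sprintf(
        "beta values must lie in [0,1]; first violation at probe '%s', sample '%s' (value %g)",
        rownames(b)[i[1L]], colnames(b)[i[2L]], b[bad[1L]]))
    }
    if (anyDuplicated(rownames(b)))
      msg <- c(msg, paste0("duplicated probe id(s): ",
                           paste(unique(rownames(b)[duplicated(rownames(b))]), collapse = ", ")))
    if (anyDuplicated(colnames(b)))
      msg <- c(msg, "duplicated sample id(s)")
  }
  if ("detectionP" %in% assayNames(object)) {
    dp <- assay(object, "detectionP")
    if (any(!is.na(dp) & (dp < 0 | dp > 1)))
      msg <- c(msg, "detection p-values must lie in [0,1]")
  }
  dmsg <- .checkDesignFrame(colData(object))
  if (!is.null(dmsg)) msg <- c(msg, dmsg)
  if (length(msg)) msg else TRUE
})

setValidity("ExprExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    e <- assay(object, "exprs")
    if (anyDuplicated(rownames(e)))
      msg <- c(msg, paste0("duplicated gene symbol(s): ",
                           paste(unique(rownames(e)[duplicated(rownames(e))]), collapse = ", ")))
    if (any(!is.finite(e)))
      msg <- c(msg, "expression values must be finite")
  }
  dmsg <- .checkDesignFrame(colData(object))
  if (!is.null(dmsg)) msg <- c(msg, dmsg)
  if (length(msg)) msg else TRUE
})

#' Construct a MethylExperiment
#'
#' @param beta numeric matrix of beta values in [0, 1], CpGs in rows
#'   (rownames = probe ids), samples in columns (colnames = sample ids).
#' @param design data.frame with columns \code{sample_id} and \code{group}
#'   (\code{"fetal"}/\code{"adult"}) plus optional numeric covariates; must
#'   cover every column of \code{beta}.
#' @param detectionP optional matrix of detection p-values, same
#'   dimensions and dimnames as \code{beta}.
#' @param annotation optional probe annotation data.frame (manifest-style
#'   columns, see \code{\link{readCpGAnnotation}}); matched to probes by its
#'   \code{IlmnID} column.
#' @return a \linkS4class{MethylExperiment}
#' @examples
#' b <- matrix(runif(12), 2, 6,
#'             dimnames = list(c("cg01", "cg02"), paste0("S", 1:6)))
#' des <- data.frame(sample_id = paste0("S", 1:6),
#'                   group = rep(c("fetal", "adult"), each = 3))
#' me <- MethylExperiment(b, des)
#' @export
MethylExperiment <- function(beta, design, detectionP = NULL, annotation = NULL) {
  design <- .validateDesign(design, colnames(beta))
  beta <- beta[, design$sample_id, drop = FALSE]
  assays <- list(beta = beta)
  if (!is.null(detectionP)) {
    if (!identical(dim(detectionP), dim(beta)) ||
        !identical(rownames(detectionP), rownames(beta)))
      stop("detectionP must have the same dimensions and probe ids as beta")
    assays$detectionP <- detectionP[, design$sample_id, drop = FALSE]
  }
  rd <- NULL
  if (!is.null(annotation)) {
    idx <- match(rownames(beta), annotation$IlmnID)
    if (anyNA(idx))
      stop("probes missing from annotation: ",
           paste(utils::head(rownames(beta)[is.na(idx)], 5L), collapse = ", "))
    rd <- DataFrame(annotation[idx, setdiff(colnames(annotation), "IlmnID"),
                               drop = FALSE])
    rownames(rd) <- rownames(beta)
  }
  cd <- DataFrame(design[, setdiff(colnames(design), "sample_id"), drop = FALSE])
  rownames(cd) <- design$sample_id
  se <- SummarizedExperiment(assays = assays, colData = cd)
  if (!is.null(rd)) rowData(se) <- rd
  new("MethylExperiment", se)
}

#' Construct an ExprExperiment
#'
#' @param exprs numeric matrix of normalized log2 expression values, genes in
#'   rows (rownames = gene symbols), samples in columns.
#' @inheritParams MethylExperiment
#' @return an \linkS4class{ExprExperiment}
#' @export
ExprExperiment <- function(exprs, design) {
  design <- .validateDesign(design, colnames(exprs))
  exprs <- exprs[, design$sample_id, drop = FALSE]
  cd <- DataFrame(design[, setdiff(colnames(design), "sample_id"), drop = FALSE])
  rownames(cd) <- design$sample_id
  new("ExprExperiment",
      SummarizedExperiment(assays = list(exprs = exprs), colData = cd))
}

# Check a sample design table against a set of matrix columns: all columns
# covered, groups restricted to fetal/adult, >= 2 samples per group.
.validateDesign <- function(design, sample_ids) {
  if (!all(c("sample_id", "group") %in% colnames(design)))
    stop("design must have columns 'sample_id' and 'group'")
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample id(s) in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(as.character(design$group)), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s) in design: ", paste(bad, collapse = ", "))
  tab <- table(factor(design$group, levels = GROUP_LEVELS))
  if (any(tab < 2L))
    stop("each group needs at least 2 samples; got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, design$sample_id)
    if (length(miss))
      stop("matrix sample(s) missing from design: ", paste(miss, collapse = ", "))
    design <- design[design$sample_id %in% sample_ids, , drop = FALSE]
  }
  design$group <- factor(as.character(design$group), levels = GROUP_LEVELS)
  design
}

#' @describeIn MethylExperiment-class the beta-value matrix
#' @param object,x a \code{MethylExperiment}
#' @export
betaValues <- function(object) assay(object, "beta")

#' @describeIn MethylExperiment-class the detection p-value matrix, or NULL
#' @export
detectionP <- function(object) {
  if ("detectionP" %in% assayNames(object)) assay(object, "detectionP") else NULL
}

#' @describeIn ExprExperiment-class the log2 expression matrix
#' @param object an \code{ExprExperiment}
#' @export
exprValues <- function(object) assay(object, "exprs")

#' Sample group factor of a methylation or expression experiment
#'
#' @param object a \code{MethylExperiment} or \code{ExprExperiment}
#' @return factor with levels \code{fetal}, \code{adult}, named by sample id
#' @export
sampleGroups <- function(object) {
  g <- factor(as.character(colData(object)$group), levels = GROUP_LEVELS)
  names(g) <- colnames(object)
  g
}

#' Probe annotation of a MethylExperiment as a data.frame
#'
#' @param object a \code{MethylExperiment}
#' @return data.frame with the manifest-style annotation columns plus
#'   \code{IlmnID}
#' @export
cpgAnnotation <- function(object) {
  rd <- as.data.frame(rowData(object))
  data.frame(IlmnID = rownames(object), rd, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

setMethod("show", "MethylExperiment", function(object) {
  cat(sprintf("MethylExperiment: %d CpGs x %d samples (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%s=%d", GROUP_LEVELS,
                            table(factor(colData(object)$group, GROUP_LEVELS))),
                    collapse = ", ")))
  cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (ncol(rowData(object)))
    cat("annotation:", paste(colnames(rowData(object)), collapse = ", "), "\n")
})

setMethod("show", "ExprExperiment", function(object) {
  cat(sprintf("ExprExperiment: %d genes x %d samples (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%s=%d", GROUP_LEVELS,
                            table(factor(colData(object)$group, GROUP_LEVELS))),
                    collapse = ", ")))
})
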