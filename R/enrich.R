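#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between a query gene list and a gene set, given the universe:
#' P(X >= overlap) with X ~ Hypergeometric(|set|, |universe| - |set|,
#' |query|).
#'
#' @param query character vector of query genes (must lie in the universe)
#' @param geneSet character vector, the gene set (intersected with the
#'   universe)
#' @param universe character vector of all eligible genes
#' @return list with \code{overlap}, \code{set_size}, \code{query_size},
#'   \code{universe_size}, \code{p_value}
#' @export
hypergeometricORA <- function(query, geneSet, universe) {
  query <- unique(query); universe <- unique(universe)
  out <- setdiff(query, universe)
  if (length(out))
    stop("query gene(s) outside universe: ",
         paste(utils::head(out, 5L), collapse = ", "))
  geneSet <- intersect(unique(geneSet), universe)
  k <- length(intersect(query, geneSet))
  p <- stats::phyper(k - 1L, length(geneSet),
                     length(universe) - length(geneSet),
                     length(query), lower.tail = FALSE)
  list(overlap = k, set_size = length(geneSet), query_size = length(query),
       universe_size = length(universe), p_value = p)
}

#' Read gene sets in GMT format
#'
#' @param path path to a GMT file (set name, description, then member genes,
#'   tab-separated)
#' @return named list of character vectors
#' @export
readGeneSets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets
}

#' @rdname readGeneSets
#' @param sets named list of character vectors
#' @export
writeGeneSets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Control-gene-set-calibrated enrichment
#'
#' Scores the query gene list against every collection set with the
#' hypergeometric upper-tail test, then calibrates significance against
#' \code{kControls} random control gene lists of the same size drawn
#' without replacement from a pool of similarly expressed genes: a query
#' enrichment is flagged significant only when its p-value is strictly
#' below the minimum p-value observed across all control scores (the
#' global-minimum, strictest reading).
#'
#' @param query character vector of query genes
#' @param collections named list of gene sets
#' @param similarPool character vector of similarly expressed genes to draw
#'   controls from (must contain at least \code{kControls * length(query)}
#'   genes so each control can match the query size)
#' @param universe universe for the hypergeometric test
#' @param kControls number of control sets (default 5)
#' @param seed RNG seed (mandatory; controls are the only stochastic step)
#' @return list with \code{results} (data.frame: set, overlap, p_value,
#'   significant), \code{threshold} (minimum control p),
#'   \code{control_p} (matrix, controls x sets)
#' @export
controlCalibratedEnrichment <- function(query, collections, similarPool,
                                        universe, kControls = 5, seed) {
  if (missing(seed)) stop("seed is required")
  query <- unique(query)
  similarPool <- unique(setdiff(similarPool, query))
  if (length(similarPool) < kControls * length(query))
    stop(sprintf("similar pool too small: need %d genes, have %d",
                 kControls * length(query), length(similarPool)))
  score <- function(g) vapply(collections, function(s)
    hypergeometricORA(g, s, universe)$p_value, numeric(1))
  queryP <- score(query)
  ctrlP <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(kControls), function(i)
      score(sample(similarPool, length(query)))))
  })
  colnames(ctrlP) <- names(collections)
  threshold <- min(ctrlP)
  res <- data.frame(set = names(collections),
                    overlap = vapply(collections, function(s)
                      length(intersect(query, intersect(s, universe))),
                      integer(1)),
                    p_value = unname(queryP),
                    significant = unname(queryP) < threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(results = res, threshold = threshold, control_p = ctrlP)
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
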