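#' Hypergeometric over-representation analysis
#'
#' Tests whether a query protein list overlaps each gene set more than
#' expected by chance when drawing the query from the assay universe.
#' Per set, \code{p = P(X >= k)} for X hypergeometric with universe size M,
#' set size K (after intersecting the set with the universe) and query size
#' n; exact upper-tail summation (no normal approximation), followed by
#' Benjamini-Hochberg adjustment across the tested sets.
#'
#' @param query character vector of protein ids of interest. Ids outside
#'   the universe are dropped with a record.
#' @param universe character vector: all proteins that could have been
#'   selected (e.g. every assay passing QC on the panel).
#' @param collection named list of gene sets (see \code{\link{readGMT}}).
#' @param minOverlap smallest overlap k for a set to be tested (default 1;
#'   0 tests all sets, with p = 1 exactly when k = 0).
#' @param minSetSize smallest in-universe set size tested (default 3).
#' @return data.frame(set_name, k, K, n, M, p, p_adj) sorted by p; dropped
#'   query ids in \code{attr(, "droppedQuery")}.
#' @export
ora <- function(query, universe, collection, minOverlap = 1, minSetSize = 3) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(query)
  dropped <- setdiff(query, universe)
  query <- intersect(query, universe)
  M <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    K <- length(s)
    if (K < minSetSize) return(NULL)
    k <- length(intersect(s, query))
    if (k < minOverlap) return(NULL)
    p <- if (n == 0 || k == 0) 1 else
      stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, M = M, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_name = character(), k = integer(), K = integer(),
                      n = integer(), M = integer(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE)
  else {
    out$p_adj <- bhAdjust(out$p)
    out <- out[order(out$p, out$set_name), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "droppedQuery") <- dropped
  out
}
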