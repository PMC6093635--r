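## Over-representation analysis of gene lists against GMT libraries:
## hypergeometric upper tail (equivalent to one-sided Fisher) with
## Benjamini-Hochberg correction across the library.

#' Hypergeometric upper-tail probability of an overlap
#'
#' Probability of drawing at least `k` members of a `K_set`-gene set in
#' `n_query` draws without replacement from a universe of `N_universe`
#' genes. Identical to the one-sided Fisher exact test on the corresponding
#' 2x2 table.
#'
#' @param k observed overlap.
#' @param K_set set size (restricted to the universe).
#' @param n_query query size (restricted to the universe).
#' @param N_universe universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_tail <- function(k, K_set, n_query, N_universe) {
  ok <- k >= 0 && K_set >= 0 && n_query >= 0 &&
    k <= min(K_set, n_query) && K_set <= N_universe && n_query <= N_universe
  if (!ok) stopf("inconsistent hypergeometric counts")
  phyper(k - 1, K_set, N_universe - K_set, n_query, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Explicit step-up implementation: from the largest p downwards,
#' `p_adj(i) = min(p_adj(i+1), p(i) * n / i)`, capped at 1; input order is
#' preserved in the output.
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stopf("p-values must lie in (0, 1]")
  n <- length(pvals)
  ord <- order(pvals)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, pvals[ord[i]] * n / i)
    adj[ord[i]] <- running
  }
  adj
}

#' Gene-set over-representation of a query gene list
#'
#' Every set with a nonzero size after restriction to the universe is tested
#' with [hypergeom_tail()]; BH correction is applied across all tested sets.
#' Query genes outside the universe are dropped with a warning. Gene names
#' are compared case-insensitively (uppercased).
#'
#' @param query character vector of gene names.
#' @param library a `gene_set_library` (or named list of gene vectors).
#' @param universe background gene names (e.g. all genes that entered the
#'   gene-level testing stage).
#' @return data.frame sorted by raw p with columns `set, k, K_set, n_query,
#'   N_universe, p, p_bh, overlap_genes` (semicolon-joined).
#' @export
enrich <- function(query, library, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stopf("empty universe")
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warnf("dropping %d query gene(s) outside the universe", length(outside))
    query <- setdiff(query, outside)
  }
  empty <- data.frame(set = character(), k = integer(), K_set = integer(),
                      n_query = integer(), N_universe = integer(),
                      p = numeric(), p_bh = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE)
  if (length(query) == 0) {
    warnf("empty query after restriction to the universe")
    return(empty)
  }
  rows <- lapply(names(library), function(nm) {
    set_u <- intersect(toupper(library[[nm]]), universe)
    if (length(set_u) == 0) return(NULL)
    overlap <- intersect(set_u, query)
    data.frame(set = nm, k = length(overlap), K_set = length(set_u),
               n_query = length(query), N_universe = length(universe),
               p = hypergeom_tail(length(overlap), length(set_u),
                                  length(query), length(universe)),
               overlap_genes = paste(sort(overlap), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$p_bh <- bh_adjust(out$p)
  out <- out[order(out$p, out$set),
             c("set", "k", "K_set", "n_query", "N_universe", "p", "p_bh",
               "overlap_genes")]
  rownames(out) <- NULL
  out
}
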