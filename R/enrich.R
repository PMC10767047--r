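#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for enrichment in a query gene list against a gene
#' universe with the exact hypergeometric upper tail, P(X >= k), where k is
#' the query/set overlap, K the set size within the universe, n the query
#' size and N the universe size. P-values are Benjamini-Hochberg adjusted
#' across sets. Query genes outside the universe are dropped with a warning.
#'
#' @param query_genes character vector of query gene symbols (non-empty)
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()])
#' @param universe character vector of all assayable genes
#' @return data.frame sorted by p: `set`, `k` (overlap), `K` (set size in
#'   universe), `n` (query size), `N` (universe size), `p`, `p_adj`,
#'   `genes` (comma-separated overlap)
#' @export
hypergeometric_ora <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe, dropped", length(outside))
    query <- intersect(query, universe)
  }
  if (!length(query)) stopf("empty query after universe filtering")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    ov <- intersect(set, query)
    k <- length(ov)
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(ov), collapse = ","))
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p), c("set", "k", "K", "n", "N", "p", "p_adj", "genes")]
  rownames(res) <- NULL
  res
}
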