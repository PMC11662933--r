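#' Hypergeometric gene-set over-representation with fold enrichment
#'
#' For each named gene set: k = overlap with the query, n = query size,
#' K = set size within the universe, M = universe size; p is the
#' hypergeometric upper tail P(X >= k), adjusted across sets by
#' Benjamini-Hochberg; foldEnrichment is the GeneRatio (k/n) divided by the
#' BgRatio (K/M). Records are ordered by adjusted p-value and then by fold
#' enrichment, descending.
#'
#' @param query character vector of genes (must lie in the universe).
#' @param collections named list of character vectors (gene sets); each set
#'   is intersected with the universe before testing.
#' @param universe character vector of all tested genes.
#' @return data.frame: set_id, k_overlap, n_query, set_size, universe_size,
#'   gene_ratio, bg_ratio, fold_enrichment, p_value, padj.
#' @export
gene_set_enrichment <- function(query, collections, universe) {
  universe <- unique(universe)
  M <- length(universe)
  assert_that(M > 0, "empty universe")
  query <- unique(query)
  assert_that(all(query %in% universe), "query must be a subset of universe")
  n <- length(query)
  rows <- lapply(names(collections), function(id) {
    set <- intersect(unique(collections[[id]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k_overlap = k, n_query = n, set_size = K,
               universe_size = M,
               gene_ratio = k / n, bg_ratio = K / M,
               fold_enrichment = if (K > 0) (k / n) / (K / M) else 0,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p_value, method = "BH")
  out[order(out$padj, -out$fold_enrichment), , drop = FALSE]
}
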