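#' Hypergeometric gene-set over-representation with BH FDR
#'
#' One-sided (upper tail) hypergeometric test per term: with a universe of
#' `G` genes, a term of size `K` (after intersecting members with the
#' universe) and a query of size `n`, the p-value is `P(X >= k)` for the
#' observed overlap `k`. Benjamini-Hochberg FDR is applied across the
#' tested terms of the collection. Results are sorted by p-value, ties by
#' term id.
#'
#' @param query_genes character vector of query gene symbols (e.g. DEGs).
#'   Genes outside the universe are dropped with a warning.
#' @param collection a `gene_sets` object ([read_gmt()] or
#'   [simulate_genesets()]).
#' @param universe character vector of background genes; the conventional
#'   choice is every annotated, non-pseudogene gene on the array.
#' @return data.frame: `term_id`, `k` (overlap), `K` (term size), `n`
#'   (query size), `G` (universe size), `p_value`, `fdr`, `neg_log10_p`.
#' @export
enrich_gene_sets <- function(query_genes, collection, universe) {
  universe <- unique(universe)
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) stop("empty query after universe intersection")
  G <- length(universe); n <- length(query)
  res <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, G - K, n, lower.tail = FALSE)
    data.frame(term_id = id, k = k, K = K, n = n, G = G, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_value, "BH")
  out$neg_log10_p <- -log10(out$p_value)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
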