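# Independent enumeration oracles and small fixture builders shared across
# the suite. The oracles deliberately avoid phyper(): tails are summed from
# the binomial-coefficient pmf directly.

# P(X >= k) for a hypergeometric with `white` marked among `total`, drawing
# `draws`, by pmf enumeration
enum_upper_tail <- function(k, white, total, draws) {
  hi <- min(white, draws)
  if (k > hi) return(0)
  i <- max(k, max(0, draws - (total - white))):hi
  sum(exp(lchoose(white, i) + lchoose(total - white, draws - i) -
            lchoose(total, draws)))
}

# P(X <= k), same parameterization
enum_lower_tail <- function(k, white, total, draws) {
  lo <- max(0, draws - (total - white))
  if (k < lo) return(0)
  i <- lo:min(k, min(white, draws))
  sum(exp(lchoose(white, i) + lchoose(total - white, draws - i) -
            lchoose(total, draws)))
}

# tiny expression matrix from explicit log2 rows
make_expr <- function(rows, n_case, n_control, probe_ids = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(probe_ids)) probe_ids <- sprintf("p%02d", seq_len(nrow(m)))
  sids <- c(sprintf("case%d", seq_len(n_case)),
            sprintf("ctrl%d", seq_len(n_control)))
  dimnames(m) <- list(probe_ids, sids)
  expr_matrix(m, stats::setNames(rep(c("case", "control"),
                                     c(n_case, n_control)), sids))
}

# annotation row builder with sane defaults
make_ann <- function(probe_id, gene_symbol, chromosome = "chr1",
                     start = seq_along(probe_id) * 1000,
                     end = start + 100, strand = "+",
                     pseudogene_flag = FALSE) {
  data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
             entrez_id = seq_along(probe_id), chromosome = chromosome,
             start = start, end = end, strand = strand,
             pseudogene_flag = pseudogene_flag, stringsAsFactors = FALSE)
}

# genome ordering for n genes on one chromosome, with the given DEG flags
make_ordered <- function(n, chromosome = "chr1") {
  data.frame(chromosome = chromosome,
             gene_symbol = sprintf("g%03d", seq_len(n)),
             start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 100L,
             index = seq_len(n), stringsAsFactors = FALSE)
}

# small interaction network from an undirected edge list given as a
# two-column matrix of object names
make_network <- function(edges, gene_to_object = character(0),
                         objects = NULL) {
  interaction_network(data.frame(source = edges[, 1], target = edges[, 2],
                                 sign = 1L, stringsAsFactors = FALSE),
                      gene_to_object = gene_to_object, objects = objects)
}

small_sim_config <- function(...) {
  defaults <- list(n_genes = 300, n_chromosomes = 3, n_hotspots = 3,
                   hotspot_span_genes = 15, frac_deg = 0.15,
                   network_nodes = 800, n_hub_plants = 4, n_terms = 30,
                   term_size_range = c(5, 25), n_enriched_terms = 3,
                   seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
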