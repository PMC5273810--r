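#' Map dataset genes onto network objects
#'
#' Resolves gene symbols through the network's gene-to-object mapping and
#' returns the distinct objects. Several genes may share one object (a
#' "group" object such as two myxovirus-resistance paralogs mapping to one
#' protein group), so the mapped set can be smaller than the gene list.
#' Unmapped genes are attached as the `"unmapped"` attribute and reported
#' via message.
#'
#' @param genes character vector of gene symbols.
#' @param network an `interaction_network`.
#' @return character vector of distinct object ids, with attribute
#'   `unmapped`.
#' @export
map_genes_to_objects <- function(genes, network) {
  stopifnot(inherits(network, "interaction_network"))
  hit <- network$gene_to_object[genes]
  unmapped <- genes[is.na(hit)]
  objs <- unique(unname(hit[!is.na(hit)]))
  if (length(unmapped))
    message(length(unmapped), " gene(s) could not be mapped to objects")
  structure(objs, unmapped = unmapped)
}

# hypergeometric connectivity formulas shared by all connectivity analyses:
# A of n dataset objects among the R neighbors drawn from N background
# objects. E = nR/N; sd of the hypergeometric; z = (A-E)/sd; exact tail p
# (upper when z >= 0, lower when z < 0).
hypergeom_connectivity <- function(A, n, R, N) {
  # recycle explicitly: ifelse() below keys on its condition's length, so
  # a scalar sd with vector A would silently truncate the result
  k <- max(length(A), length(n), length(R), length(N))
  A <- rep_len(A, k); n <- rep_len(n, k)
  R <- rep_len(R, k); N <- rep_len(N, k)
  E <- n * R / N
  sd <- sqrt(n * (R / N) * (1 - R / N) * (N - n) / (N - 1))
  z <- ifelse(sd > 0, (A - E) / sd, 0)
  p <- ifelse(z >= 0,
              stats::phyper(A - 1, R, N - R, n, lower.tail = FALSE),
              stats::phyper(A, R, N - R, n, lower.tail = TRUE))
  list(E = E, sd = sd, z = z, ratio = ifelse(E > 0, A / E, NA_real_), p = p)
}

#' Connectivity statistics from raw counts
#'
#' Computes the over/under-connectivity statistic directly from its four
#' counts, without a network object: `A` dataset neighbors observed for an
#' object with `R` distinct neighbors, for a dataset of `n` objects drawn
#' from a background of `N`. Reported are the expectation `E = nR/N`, the
#' hypergeometric standard deviation, the z-score `(A - E)/sd`, the
#' connectivity ratio `A/E` and the exact tail probability (upper tail for
#' `z >= 0`, lower for `z < 0`). Vectorized over all four arguments. This
#' is the same computation [connectivity_stats()] applies after counting
#' neighbors, exposed for validating published tables that report the raw
#' counts.
#'
#' @param A observed dataset-neighbor count(s).
#' @param n dataset size(s).
#' @param R background neighbor count(s).
#' @param N background size(s).
#' @return list with elements `E`, `sd`, `z`, `ratio`, `p`.
#' @export
connectivity_from_counts <- function(A, n, R, N) {
  if (any(A < 0 | n < 0 | R < 0 | N < 1 | A > n | A > R | n > N | R > N))
    stop("counts must satisfy 0 <= A <= min(n, R) and n, R <= N")
  hypergeom_connectivity(A, n, R, N)
}

# distinct-neighbor adjacency on the undirected projection, self excluded
undirected_neighbors <- function(network) {
  gu <- igraph::as_undirected(network$graph, mode = "collapse")
  gu <- igraph::simplify(gu, remove.loops = TRUE, remove.multiple = TRUE)
  adj <- igraph::as_adj_list(gu, mode = "all")
  nms <- igraph::V(gu)$name
  stats::setNames(lapply(adj, function(v) nms[as.integer(v)]), nms)
}

#' Over-connectivity statistics for one network object
#'
#' The relative-connectivity statistic of a dataset against a curated
#' interaction background: for an object with `R` distinct neighbors among
#' the `N` background objects, and a dataset of `n` mapped objects, the
#' observed count `A` of neighbors inside the dataset is compared with the
#' hypergeometric expectation `E = nR/N`. Reported are `E`, the
#' connectivity ratio `A/E`, the z-score `(A - E)/sd`, and the exact tail
#' probability (upper tail for `z >= 0`, lower for `z < 0`). The object
#' itself never counts among its own neighbors.
#'
#' @param object_id object to score.
#' @param dataset_objects character vector of dataset-mapped objects
#'   (see [map_genes_to_objects()]).
#' @param network an `interaction_network`.
#' @param alpha significance level for the direction call (default 0.05,
#'   on the unadjusted tail p).
#' @return one-row data.frame: `object_id`, `A`, `n`, `R`, `N`, `E`,
#'   `ratio`, `z`, `p_value`, `direction` (over/under/none/isolated).
#' @export
connectivity_stats <- function(object_id, dataset_objects, network,
                               alpha = 0.05) {
  stopifnot(inherits(network, "interaction_network"))
  if (!object_id %in% network$objects)
    stop("unknown object: ", object_id)
  nbrs <- undirected_neighbors(network)[[object_id]]
  connectivity_row(object_id, nbrs, dataset_objects, network$N, alpha)
}

connectivity_row <- function(object_id, nbrs, dataset_objects, N, alpha) {
  n <- length(unique(dataset_objects))
  R <- length(nbrs)
  if (R == 0)
    return(data.frame(object_id = object_id, A = NA_integer_, n = n,
                      R = 0L, N = N, E = NA_real_, ratio = NA_real_,
                      z = NA_real_, p_value = NA_real_,
                      direction = "isolated", stringsAsFactors = FALSE))
  A <- length(intersect(nbrs, setdiff(dataset_objects, object_id)))
  st <- hypergeom_connectivity(A, n, R, N)
  direction <- if (st$p < alpha && st$z > 0) "over"
               else if (st$p < alpha && st$z < 0) "under" else "none"
  data.frame(object_id = object_id, A = A, n = n, R = R, N = N,
             E = st$E, ratio = st$ratio, z = st$z, p_value = st$p,
             direction = direction, stringsAsFactors = FALSE)
}

#' Connectivity statistics for many candidate objects
#'
#' @param dataset_objects dataset-mapped object ids.
#' @param network an `interaction_network`.
#' @param candidates objects to score (default: every background object
#'   with at least one edge).
#' @param alpha significance level for direction calls.
#' @return data.frame of per-object connectivity rows.
#' @export
connectivity_table <- function(dataset_objects, network, candidates = NULL,
                               alpha = 0.05) {
  stopifnot(inherits(network, "interaction_network"))
  adj <- undirected_neighbors(network)
  if (is.null(candidates))
    candidates <- names(adj)[lengths(adj) > 0]
  rows <- lapply(candidates, function(o)
    connectivity_row(o, adj[[o]], dataset_objects, network$N, alpha))
  do.call(rbind, rows)
}

#' Significantly over-connected objects
#'
#' Objects whose neighbor count inside the dataset exceeds the
#' hypergeometric expectation at tail p < `alpha`, sorted by p-value.
#' Under-connected objects (a deficit at p < `alpha`) are attached as the
#' `"under"` attribute; BH-adjusted p-values are reported in both.
#'
#' @inheritParams connectivity_table
#' @return data.frame of over-connected objects (columns as
#'   [connectivity_stats()] plus `fdr`), attribute `under` with the
#'   under-connected rows.
#' @export
overconnected_set <- function(dataset_objects, network, alpha = 0.05,
                              candidates = NULL) {
  tab <- connectivity_table(dataset_objects, network, candidates, alpha)
  scored <- tab[tab$direction != "isolated", , drop = FALSE]
  scored$fdr <- stats::p.adjust(scored$p_value, "BH")
  over <- scored[scored$direction == "over", , drop = FALSE]
  over <- over[order(over$p_value, over$object_id), , drop = FALSE]
  under <- scored[scored$direction == "under", , drop = FALSE]
  under <- under[order(under$p_value, under$object_id), , drop = FALSE]
  structure(over, under = under)
}

#' Pairings among over-connected objects
#'
#' All unordered pairs of over-connected objects joined by at least one
#' edge (either direction), plus the per-object count of such pairings —
#' the "most pairings" summary of an over-connected set.
#'
#' @param over_ids character vector of over-connected object ids.
#' @param network an `interaction_network`.
#' @return list with `pairs` (data.frame `u`, `v`) and `counts` (named
#'   integer vector, sorted decreasingly).
#' @export
overconnected_pairs <- function(over_ids, network) {
  stopifnot(inherits(network, "interaction_network"))
  if (length(over_ids) == 0) stop("empty over-connected set")
  gu <- igraph::as_undirected(network$graph, mode = "collapse")
  gu <- igraph::simplify(gu)
  sub <- igraph::induced_subgraph(gu, intersect(over_ids,
                                                igraph::V(gu)$name))
  ed <- igraph::as_data_frame(sub, what = "edges")
  pairs <- if (nrow(ed)) {
    u <- pmin(ed$from, ed$to); v <- pmax(ed$from, ed$to)
    data.frame(u = u, v = v, stringsAsFactors = FALSE)
  } else data.frame(u = character(0), v = character(0))
  counts <- table(factor(c(pairs$u, pairs$v), levels = over_ids))
  counts <- sort(stats::setNames(as.integer(counts), names(counts)),
                 decreasing = TRUE)
  list(pairs = pairs, counts = counts)
}

#' Rank transcription factors by target-set over-connectivity with DEGs
#'
#' Scores every TF's curated target set against the DEG list with the same
#' hypergeometric connectivity statistic (`A` = targets among DEGs, `R` =
#' target-set size, `n` = DEGs in the universe, `N` = universe size) and
#' ranks by z-score. TFs absent from the DEG list are scored too — this is
#' how "hidden" regulators whose targets are dysregulated surface at the
#' top of the ranking.
#'
#' @param tf_targets named list: TF id -> character vector of target genes.
#'   TFs with empty target sets (after universe intersection) are skipped
#'   with a warning.
#' @param deg_genes character vector of DEG gene symbols.
#' @param universe character vector of background genes.
#' @param alpha significance level for direction calls.
#' @return data.frame ranked by decreasing z: `tf`, `A`, `n`, `R`, `N`,
#'   `E`, `ratio`, `z`, `p_value`, `direction`, `in_deg_list`.
#' @export
regulator_enrichment <- function(tf_targets, deg_genes, universe,
                                 alpha = 0.05) {
  universe <- unique(universe)
  degs <- intersect(unique(deg_genes), universe)
  n <- length(degs); N <- length(universe)
  rows <- lapply(names(tf_targets), function(tf) {
    targets <- intersect(unique(tf_targets[[tf]]), universe)
    if (length(targets) == 0) {
      warning("TF '", tf, "' has no targets in the universe; skipped")
      return(NULL)
    }
    A <- length(intersect(targets, degs))
    st <- hypergeom_connectivity(A, n, length(targets), N)
    direction <- if (st$p < alpha && st$z > 0) "over"
                 else if (st$p < alpha && st$z < 0) "under" else "none"
    data.frame(tf = tf, A = A, n = n, R = length(targets), N = N,
               E = st$E, ratio = st$ratio, z = st$z, p_value = st$p,
               direction = direction, in_deg_list = tf %in% deg_genes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(tf = character(0), A = integer(0), n = integer(0),
                      R = integer(0), N = integer(0), E = numeric(0),
                      ratio = numeric(0), z = numeric(0),
                      p_value = numeric(0), direction = character(0),
                      in_deg_list = logical(0), stringsAsFactors = FALSE))
  out[order(-out$z, out$p_value, out$tf), , drop = FALSE]
}

#' Topology summary of the dataset within the background network
#'
#' Per dataset object, in- and out-degrees split by whether the opposite
#' endpoint is itself in the dataset or in the remaining background, plus
#' the mean local clustering coefficient (undirected projection) of the
#' dataset-induced subgraph and of the whole background. Nodes of degree
#' < 2 have an undefined local coefficient and are excluded from the means.
#'
#' @param dataset_objects dataset-mapped object ids.
#' @param network an `interaction_network`.
#' @return list with `degrees` (data.frame: `object_id`, `in_dataset`,
#'   `in_background`, `out_dataset`, `out_background`),
#'   `clustering_dataset` and `clustering_background`.
#' @export
topology_summary <- function(dataset_objects, network) {
  stopifnot(inherits(network, "interaction_network"))
  ed <- igraph::as_data_frame(network$graph, what = "edges")
  in_set <- function(x) x %in% dataset_objects
  rows <- lapply(dataset_objects, function(o) {
    incoming <- ed$from[ed$to == o]
    outgoing <- ed$to[ed$from == o]
    data.frame(object_id = o,
               in_dataset = sum(in_set(incoming)),
               in_background = sum(!in_set(incoming)),
               out_dataset = sum(in_set(outgoing)),
               out_background = sum(!in_set(outgoing)),
               stringsAsFactors = FALSE)
  })
  gu <- igraph::simplify(igraph::as_undirected(network$graph,
                                               mode = "collapse"))
  cc_bg <- igraph::transitivity(gu, type = "local", isolates = "NaN")
  sub <- igraph::induced_subgraph(gu, intersect(dataset_objects,
                                                igraph::V(gu)$name))
  cc_ds <- igraph::transitivity(sub, type = "local", isolates = "NaN")
  list(degrees = do.call(rbind, rows),
       clustering_dataset = mean(cc_ds, na.rm = TRUE),
       clustering_background = mean(cc_bg, na.rm = TRUE))
}
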