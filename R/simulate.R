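#' Simulation configuration for the synthetic study generator
#'
#' Parameterizes a two-group blood-microarray study with planted structure:
#' differentially expressed genes (a minority, mostly down-regulated),
#' redundant probes per gene, genomic hot spots of clustered DEG loci, a
#' scale-free interaction background with planted over-connected hubs, and
#' a gene-set collection with planted enriched terms. Defaults emulate the
#' study regime this package targets: 8 cases vs 6 controls, ~12,600 probes
#' over ~9,000 genes, fold changes 1.5-4 with ~95% down-regulation, and a
#' 26,494-object interaction background.
#'
#' @param n_cases,n_controls sample counts per group.
#' @param n_genes number of genes on the array.
#' @param probes_per_gene_distribution named numeric vector: probability of
#'   a gene being measured by 1, 2, 3, ... probes.
#' @param frac_deg fraction of genes planted as differentially expressed.
#' @param deg_direction_frac_down fraction of planted DEGs down-regulated.
#' @param fc_range linear-scale fold-change range for planted DEGs
#'   (lower bound must exceed 1).
#' @param noise_sd per-probe Gaussian noise SD on the log2 scale.
#' @param n_chromosomes chromosomes over which genes are laid out.
#' @param n_hotspots number of planted DEG-dense genomic intervals.
#' @param hotspot_span_genes consecutive genes spanned by each hot spot.
#' @param frac_pseudogene fraction of genes flagged pseudogene or left
#'   unannotated (these are trimmed during probe collapsing).
#' @param network_nodes background interaction-network size (objects).
#' @param network_attachment edges added per node (preferential attachment).
#' @param n_hub_plants number of planted over-connected hubs.
#' @param hub_neighborhood_deg_frac fraction of each planted hub's
#'   neighbors mapped to DEG genes.
#' @param n_terms number of gene sets generated.
#' @param term_size_range min/max gene-set size.
#' @param n_enriched_terms number of terms planted as DEG-enriched
#'   (>= 60% of members drawn from planted DEGs).
#' @param seed integer seed; identical configs give byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 8, n_controls = 6,
                       n_genes = 9000,
                       probes_per_gene_distribution = c("1" = 0.7, "2" = 0.2, "3" = 0.1),
                       frac_deg = 0.011,
                       deg_direction_frac_down = 0.95,
                       fc_range = c(1.5, 4),
                       noise_sd = 0.5,
                       n_chromosomes = 23,
                       n_hotspots = 6,
                       hotspot_span_genes = 20,
                       frac_pseudogene = 0.05,
                       network_nodes = 26494,
                       network_attachment = 3,
                       n_hub_plants = 16,
                       hub_neighborhood_deg_frac = 0.5,
                       n_terms = 200,
                       term_size_range = c(10, 100),
                       n_enriched_terms = 5,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_cases", "n_controls", "n_genes", "n_chromosomes",
              "network_nodes", "network_attachment", "n_terms")
  for (f in counts)
    if (cfg[[f]] < 1) stop("`", f, "` must be a positive count")
  for (f in c("frac_deg", "deg_direction_frac_down", "frac_pseudogene",
              "hub_neighborhood_deg_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("`", f, "` must lie in [0,1]")
  if (n_hotspots < 0 || n_hub_plants < 0 || n_enriched_terms < 0)
    stop("plant counts must be non-negative")
  if (fc_range[1] <= 1 || fc_range[2] < fc_range[1])
    stop("`fc_range` lower bound must exceed 1 and be <= upper bound")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  p <- probes_per_gene_distribution
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
    stop("`probes_per_gene_distribution` must be a probability vector")
  if (term_size_range[1] < 1 || term_size_range[2] < term_size_range[1])
    stop("`term_size_range` invalid")
  if (n_enriched_terms > n_terms)
    stop("`n_enriched_terms` exceeds `n_terms`")
  if (network_nodes < n_hub_plants)
    stop("`network_nodes` must be >= `n_hub_plants`")
  # hot spots are assigned to chromosomes round-robin; every chromosome must
  # be able to host its share of spans
  genes_per_chrom <- floor(n_genes / n_chromosomes)
  spots_per_chrom <- ceiling(n_hotspots / n_chromosomes)
  if (n_hotspots > 0 && spots_per_chrom * hotspot_span_genes > genes_per_chrom)
    stop("hot spots exceed chromosome capacity: ", spots_per_chrom,
         " span(s) of ", hotspot_span_genes, " genes on a chromosome of ",
         genes_per_chrom, " genes")
  structure(cfg, class = "sim_config")
}

# DEGs planted inside each hot spot: enough to dominate the interval but
# leaving budget for scattered DEGs elsewhere (>= 3 required downstream)
hotspot_plant_count <- function(span) max(3L, as.integer(round(0.3 * span)))

# sample() treats a length-1 numeric first argument as 1:x; always index
# per-stage derived seed, wrapped so seeds near .Machine$integer.max do
# not overflow to NA
derived_seed <- function(seed, offset)
  as.integer((as.double(seed) + offset) %% .Machine$integer.max)

sample_vec <- function(x, size = length(x), replace = FALSE, prob = NULL)
  x[sample.int(length(x), size, replace = replace, prob = prob)]

#' Simulate a probe-level case-control expression study
#'
#' Lays `n_genes` genes out over `n_chromosomes` chromosomes, plants
#' `n_hotspots` intervals of consecutive genes dense in DEGs, draws
#' per-gene probe counts, and generates log2 intensities: every probe of a
#' gene scatters (i.i.d. Gaussian, `noise_sd`) around the gene's group
#' mean, and planted DEG genes carry a case-minus-control log2 difference
#' of `sign * log2(FC)` with FC drawn uniformly from `fc_range` and sign
#' negative with probability `deg_direction_frac_down`.
#'
#' @param config a [sim_config()].
#' @return A list with `expression` ([expr_matrix()]), `annotation`
#'   (data.frame: probe_id, gene_symbol, entrez_id, chromosome, start, end,
#'   strand, pseudogene_flag) and `truth` (list: `deg_genes` named numeric of
#'   signed true fold changes, `hotspot_intervals`, `gene_universe`, plus
#'   placeholders filled by the network and gene-set simulators).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("G%05d", seq_len(ng))

  # genome layout: contiguous blocks of genes per chromosome, fixed spacing
  sizes <- rep(floor(ng / config$n_chromosomes), config$n_chromosomes)
  rem <- ng - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  chrom_of <- rep(paste0("chr", seq_len(config$n_chromosomes)), times = sizes)
  idx_in_chrom <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  start <- (idx_in_chrom - 1L) * 10000L + 1L
  end <- start + 1999L
  strand <- sample(c("+", "-"), ng, replace = TRUE)

  # plant hot spots round-robin over chromosomes at random offsets
  hotspot_intervals <- list()
  in_hotspot <- rep(FALSE, ng)
  hotspot_deg <- character(0)
  if (config$n_hotspots > 0) {
    span <- config$hotspot_span_genes
    chrom_for_spot <- rep(seq_len(config$n_chromosomes),
                          length.out = config$n_hotspots)
    for (h in seq_len(config$n_hotspots)) {
      ch <- chrom_for_spot[h]
      used <- vapply(hotspot_intervals, function(iv)
        identical(iv$chromosome, paste0("chr", ch)), logical(1))
      occupied <- unlist(lapply(hotspot_intervals[used], function(iv)
        iv$start_index:iv$end_index))
      tries <- 0L
      repeat {
        s <- sample.int(sizes[ch] - span + 1L, 1L)
        if (!length(occupied) || !any(seq(s, s + span - 1L) %in% occupied)) break
        tries <- tries + 1L
        if (tries > 1000L)
          stop("could not place hot spot ", h, " on chr", ch,
               ": chromosome too fragmented")
      }
      e <- s + span - 1L
      hotspot_intervals[[h]] <- list(chromosome = paste0("chr", ch),
                                     start_index = s, end_index = e)
      global <- which(chrom_of == paste0("chr", ch))[s:e]
      in_hotspot[global] <- TRUE
      # plant DEGs at random positions inside the interval
      k <- hotspot_plant_count(span)
      hotspot_deg <- c(hotspot_deg, genes[sample_vec(global, k)])
    }
  }

  n_deg <- round(config$frac_deg * ng)
  if (length(hotspot_deg) > n_deg)
    stop("hot-spot plants require ", length(hotspot_deg),
         " DEGs but frac_deg allows only ", n_deg)
  pool <- setdiff(genes[!in_hotspot], hotspot_deg)
  scattered <- if (n_deg > length(hotspot_deg))
    sample_vec(pool, n_deg - length(hotspot_deg)) else character(0)
  deg_genes <- c(hotspot_deg, scattered)

  fc <- stats::runif(length(deg_genes), config$fc_range[1], config$fc_range[2])
  down <- stats::runif(length(deg_genes)) < config$deg_direction_frac_down
  signed_fc <- ifelse(down, -fc, fc)
  names(signed_fc) <- deg_genes

  # pseudogene / unannotated trims drawn from non-DEG genes only
  n_pseudo <- round(config$frac_pseudogene * ng)
  trimmed <- sample_vec(setdiff(genes, deg_genes), min(n_pseudo, ng - n_deg))
  pseudo_genes <- trimmed[seq_len(floor(length(trimmed) * 2 / 3))]
  unann_genes <- setdiff(trimmed, pseudo_genes)

  # probe counts and intensities
  counts_supported <- as.integer(names(config$probes_per_gene_distribution))
  n_probes_of <- sample_vec(counts_supported, ng, replace = TRUE,
                            prob = config$probes_per_gene_distribution)
  base_mean <- stats::runif(ng, 6, 10)
  delta <- rep(0, ng)
  di <- match(deg_genes, genes)
  delta[di] <- sign(signed_fc) * log2(abs(signed_fc))

  ns <- config$n_cases + config$n_controls
  sample_ids <- c(sprintf("VL%02d", seq_len(config$n_cases)),
                  sprintf("HC%02d", seq_len(config$n_controls)))
  groups <- stats::setNames(rep(c("case", "control"),
                                c(config$n_cases, config$n_controls)),
                            sample_ids)
  gene_row <- rep(seq_len(ng), times = n_probes_of)
  np <- length(gene_row)
  probe_ids <- sprintf("%s_%d_at", genes[gene_row],
                       unlist(lapply(n_probes_of, seq_len), use.names = FALSE))
  mu <- matrix(base_mean[gene_row], nrow = np, ncol = ns)
  case_cols <- which(groups == "case")
  mu[, case_cols] <- mu[, case_cols] + delta[gene_row]
  vals <- mu + matrix(stats::rnorm(np * ns, 0, config$noise_sd), np, ns)
  dimnames(vals) <- list(probe_ids, sample_ids)

  is_unann <- genes[gene_row] %in% unann_genes
  annotation <- data.frame(
    probe_id = probe_ids,
    gene_symbol = ifelse(is_unann, NA_character_, genes[gene_row]),
    entrez_id = ifelse(is_unann, NA_integer_, gene_row),
    chromosome = ifelse(is_unann, NA_character_, chrom_of[gene_row]),
    start = ifelse(is_unann, NA_integer_, start[gene_row]),
    end = ifelse(is_unann, NA_integer_, end[gene_row]),
    strand = ifelse(is_unann, NA_character_, strand[gene_row]),
    pseudogene_flag = genes[gene_row] %in% pseudo_genes,
    stringsAsFactors = FALSE)
  validate_annotation(annotation)

  truth <- list(deg_genes = signed_fc,
                hotspot_intervals = hotspot_intervals,
                gene_universe = genes,
                trimmed_genes = sort(trimmed),
                hub_objects = character(0),
                enriched_terms = character(0))
  list(expression = expr_matrix(vals, groups),
       annotation = annotation,
       truth = truth)
}

#' Simulate a scale-free interaction background with planted hubs
#'
#' Generates an undirected preferential-attachment graph, assigns each edge
#' a random direction and effect sign, and maps genes to network objects so
#' that each planted hub's neighborhood contains at least
#' `hub_neighborhood_deg_frac` of DEG-mapped objects. Hubs are drawn from
#' moderate-degree nodes (the degree range a curated interactome reports
#' for over-connected proteins) so the DEG budget of the study regime can
#' cover the required neighborhoods. At least one many-genes-to-one-object
#' mapping is always planted.
#'
#' @param config a [sim_config()].
#' @param truth the truth record from [simulate_expression()].
#' @return A list with `network` (an `interaction_network`) and the updated
#'   `truth` (with `hub_objects` filled in).
#' @export
simulate_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derived_seed(config$seed, 1))
  nn <- config$network_nodes
  g0 <- igraph::sample_pa(nn, m = config$network_attachment,
                          directed = FALSE)
  objects <- sprintf("OBJ%05d", seq_len(nn))
  igraph::V(g0)$name <- objects
  ed <- igraph::as_data_frame(g0, what = "edges")
  flip <- stats::runif(nrow(ed)) < 0.5
  src <- ifelse(flip, ed$to, ed$from)
  tgt <- ifelse(flip, ed$from, ed$to)
  sign <- sample(c(1L, -1L, 0L), nrow(ed), replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  edges <- data.frame(source = src, target = tgt, sign = sign,
                      stringsAsFactors = FALSE)

  deg <- igraph::degree(g0)
  deg_genes <- names(truth$deg_genes)
  n_deg <- length(deg_genes)

  hub_objects <- character(0)
  deg_obj_assign <- character(0)   # objects to receive DEG genes
  if (config$n_hub_plants > 0) {
    # moderate-degree hubs: large enough to be distinctive, small enough
    # that the DEG budget can cover hub_neighborhood_deg_frac of them
    cand <- which(deg >= 8 & deg <= 30)
    if (length(cand) < config$n_hub_plants)
      cand <- order(abs(deg - 15))[seq_len(min(nn, config$n_hub_plants * 4))]
    # accept hubs greedily while the DEG budget can cover the required
    # fraction of their neighborhoods; shared neighbors count once.
    # Cheapest (lowest-degree) candidates first, random tie-break, so the
    # budget is not exhausted by expensive hubs drawn early by chance
    cand <- sample_vec(cand)
    cand <- cand[order(deg[cand])]
    hubs <- integer(0)
    for (v in cand) {
      if (length(hubs) == config$n_hub_plants) break
      nb <- setdiff(objects[as.integer(igraph::neighbors(g0, v))],
                    objects[v])
      need <- ceiling(config$hub_neighborhood_deg_frac * length(nb))
      have <- sum(nb %in% deg_obj_assign)
      extra <- if (need > have)
        sample_vec(setdiff(nb, deg_obj_assign), need - have)
      else character(0)
      if (length(deg_obj_assign) + length(extra) > n_deg) next
      hubs <- c(hubs, v)
      deg_obj_assign <- c(deg_obj_assign, extra)
    }
    if (length(hubs) < config$n_hub_plants)
      stop("hub planting needs more DEG-mapped objects than the ",
           n_deg, " DEG genes available")
    hub_objects <- objects[hubs]
  }

  # assign DEG genes: first to hub neighborhoods, remainder at random;
  # the last two leftover genes share one object (many-to-one case)
  gene_to_object <- character(0)
  shuffled_deg <- sample_vec(deg_genes)
  k <- length(deg_obj_assign)
  if (k > 0)
    gene_to_object[shuffled_deg[seq_len(k)]] <- deg_obj_assign
  leftover <- shuffled_deg[setdiff(seq_len(n_deg), seq_len(k))]
  free_obj <- setdiff(objects, c(deg_obj_assign, hub_objects))
  if (length(leftover) >= 2) {
    shared <- sample_vec(free_obj, 1)
    gene_to_object[leftover[1:2]] <- shared
    leftover <- leftover[-(1:2)]
    free_obj <- setdiff(free_obj, shared)
  }
  if (length(leftover)) {
    tgts <- sample_vec(free_obj, length(leftover))
    gene_to_object[leftover] <- tgts
    free_obj <- setdiff(free_obj, tgts)
  }
  # non-DEG genes map to the remaining objects (many-to-one if genes exceed
  # objects); ensure a many-to-one case exists even when there are <2 DEGs
  other_genes <- setdiff(truth$gene_universe, deg_genes)
  if (length(other_genes)) {
    tgts <- sample_vec(free_obj, min(length(other_genes), length(free_obj)))
    if (length(other_genes) > length(tgts))
      tgts <- c(tgts, sample_vec(tgts, length(other_genes) - length(tgts),
                                 replace = TRUE))
    gene_to_object[other_genes] <- tgts
  }
  if (!anyDuplicated(gene_to_object) && length(gene_to_object) >= 2) {
    nms <- names(gene_to_object)
    gene_to_object[nms[length(nms)]] <- gene_to_object[[nms[length(nms) - 1]]]
  }

  network <- interaction_network(edges, gene_to_object, objects)
  truth$hub_objects <- hub_objects
  list(network = network, truth = truth)
}

#' Simulate a gene-set collection with planted enriched terms
#'
#' Generates `n_terms` sets with sizes uniform over `term_size_range`;
#' the first `n_enriched_terms` draw at least 60% (here 70%, capped by the
#' DEG count) of their members from the planted DEG genes, the rest draw
#' uniformly from the gene universe.
#'
#' @param config a [sim_config()].
#' @param truth the truth record from [simulate_expression()].
#' @return A list with `gene_sets` (a `gene_sets` object) and the updated
#'   `truth` (with `enriched_terms` filled in).
#' @export
simulate_genesets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derived_seed(config$seed, 2))
  universe <- setdiff(truth$gene_universe, truth$trimmed_genes)
  lo <- config$term_size_range[1]; hi <- config$term_size_range[2]
  if (hi > length(universe))
    stop("term size range exceeds gene universe (", length(universe), ")")
  sizes <- sample_vec(seq(lo, hi), config$n_terms, replace = TRUE)
  deg_in_universe <- intersect(names(truth$deg_genes), universe)
  ids <- sprintf("TERM%04d", seq_len(config$n_terms))
  sets <- vector("list", config$n_terms)
  for (i in seq_len(config$n_terms)) {
    if (i <= config$n_enriched_terms && length(deg_in_universe)) {
      n_from_deg <- min(ceiling(0.7 * sizes[i]), length(deg_in_universe))
      from_deg <- sample_vec(deg_in_universe, n_from_deg)
      rest <- sample_vec(setdiff(universe, from_deg), sizes[i] - n_from_deg)
      sets[[i]] <- sort(c(from_deg, rest))
    } else {
      sets[[i]] <- sort(sample_vec(universe, sizes[i]))
    }
  }
  names(sets) <- ids
  desc <- stats::setNames(sprintf("synthetic gene set %d", seq_along(ids)), ids)
  truth$enriched_terms <- ids[seq_len(config$n_enriched_terms)]
  list(gene_sets = structure(sets, descriptions = desc, class = "gene_sets"),
       truth = truth)
}

#' Simulate a complete study bundle
#'
#' Runs [simulate_expression()], [simulate_network()] and
#' [simulate_genesets()] in fixed order with per-stage seeds derived from
#' `config$seed`, so the bundle and each of its parts are reproducible.
#'
#' @param config a [sim_config()].
#' @return A list: `expression`, `annotation`, `network`, `gene_sets`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config) {
  ex <- simulate_expression(config)
  nw <- simulate_network(config, ex$truth)
  gs <- simulate_genesets(config, nw$truth)
  list(expression = ex$expression, annotation = ex$annotation,
       network = nw$network, gene_sets = gs$gene_sets,
       truth = gs$truth, config = config)
}
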