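#' Pipeline configuration
#'
#' Collects every stage's threshold under one validated object. Defaults
#' are the conventional printed settings for this analysis chain: CV
#' filter 0.12, DEG selection at p < 0.05 and |FC| >= 1.4, hot spots with
#' >= 3 DEGs at scan p <= 0.05, connectivity and enrichment at 0.05.
#'
#' @param expression_path,sample_sheet_path probe matrix TSV + sample CSV.
#' @param annotation_path probe annotation TSV (tab-separated columns
#'   `probe_id, gene_symbol, entrez_id, chromosome, start, end, strand,
#'   pseudogene_flag`).
#' @param gmt_path optional gene-set GMT.
#' @param network_edges_path,network_mapping_path optional interaction
#'   network inputs.
#' @param exclude_samples sample ids dropped before analysis (the explicit
#'   quality-control exclusion list).
#' @param cv_threshold,deg_p_max,deg_fc_min,enrich_alpha,connectivity_alpha
#'   stage thresholds.
#' @param hotspot_min_k,hotspot_alpha hot-spot scan settings.
#' @param seed integer seed recorded in the manifest.
#' @param outdir output directory (created if missing).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression_path, sample_sheet_path,
                            annotation_path,
                            gmt_path = NULL,
                            network_edges_path = NULL,
                            network_mapping_path = NULL,
                            exclude_samples = character(0),
                            cv_threshold = 0.12,
                            deg_p_max = 0.05, deg_fc_min = 1.4,
                            enrich_alpha = 0.05,
                            connectivity_alpha = 0.05,
                            hotspot_min_k = 3, hotspot_alpha = 0.05,
                            seed = 1L, outdir = ".") {
  cfg <- as.list(environment())
  if (cv_threshold < 0 || deg_p_max <= 0 || deg_p_max > 1 ||
      deg_fc_min < 1 || enrich_alpha <= 0 || connectivity_alpha <= 0 ||
      hotspot_alpha <= 0 || hotspot_min_k < 1)
    stop("threshold out of range")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis chain
#'
#' Stages, in order: read + QC-exclude -> CV filter + two-way clustering +
#' PCA (signature) -> per-probe Welch tests, thresholding, probe collapsing
#' (DEGs) -> gene-set over-representation -> interactome over-connectivity
#' (if a network is configured) -> chromosomal hot-spot scan. All result
#' tables are written as TSV (hot spots additionally as BED) under
#' `outdir`, plus a JSON manifest of parameters, package version, seed and
#' per-stage record counts. Any stage failure aborts with the stage named.
#' An empty DEG list downgrades downstream stages to warnings and empty
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (invisibly also written to `manifest.json`), with
#'   a `results` attribute holding the in-memory stage outputs.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  em <- stage("input", {
    x <- read_expression(config$expression_path, config$sample_sheet_path)
    if (length(config$exclude_samples))
      x <- subset_expr(x, samples = setdiff(colnames(x$values),
                                            config$exclude_samples))
    x
  })
  annotation <- stage("input", {
    ann <- utils::read.delim(config$annotation_path,
                             stringsAsFactors = FALSE)
    ann$pseudogene_flag <- as.logical(ann$pseudogene_flag)
    validate_annotation(ann)
  })
  counts$samples <- ncol(em$values); counts$probes <- nrow(em$values)
  message("input: ", counts$probes, " probes x ", counts$samples, " samples")

  sig <- stage("signature", {
    filt <- cv_filter(em, config$cv_threshold)
    list(filtered = filt,
         sample_tree = hierarchical_cluster(filt, "samples"),
         probe_tree = hierarchical_cluster(filt, "probes",
                                           linkage = "average"),
         pca = pca_samples(em))
  })
  counts$cv_filtered_probes <- nrow(sig$filtered$values)
  message("signature: ", counts$cv_filtered_probes, " probes pass CV filter")

  degs <- stage("deg", {
    st <- test_differential(em)
    sel <- select_degs(st, config$deg_p_max, config$deg_fc_min)
    list(stats = st, selected = sel,
         table = collapse_probes(sel, annotation))
  })
  counts$deg_probes <- nrow(degs$selected)
  counts$deg_genes <- nrow(degs$table)
  message("deg: ", counts$deg_genes, " non-redundant DEGs from ",
          counts$deg_probes, " qualifying probes")
  write_table(degs$table, file.path(config$outdir, "deg_table.tsv"))
  deg_genes <- degs$table$gene_symbol
  universe <- unique(annotation$gene_symbol[!is.na(annotation$gene_symbol) &
                                              !annotation$pseudogene_flag])

  enr <- NULL
  if (!is.null(config$gmt_path)) {
    enr <- stage("enrichment", {
      if (length(deg_genes) == 0) {
        warning("no DEGs: enrichment skipped")
        NULL
      } else {
        e <- enrich_gene_sets(deg_genes, read_gmt(config$gmt_path), universe)
        write_table(e, file.path(config$outdir, "enrichment.tsv"))
        e
      }
    })
    counts$enriched_terms <-
      if (is.null(enr)) 0L else sum(enr$fdr < config$enrich_alpha)
    message("enrichment: ", counts$enriched_terms, " terms at FDR < ",
            config$enrich_alpha)
  }

  conn <- NULL
  if (!is.null(config$network_edges_path)) {
    conn <- stage("interactome", {
      if (!file.exists(config$network_edges_path))
        stop("network file not found: ", config$network_edges_path)
      nw <- read_network(config$network_edges_path,
                         config$network_mapping_path)
      if (length(deg_genes) == 0) {
        warning("no DEGs: interactome analysis skipped")
        NULL
      } else {
        objs <- map_genes_to_objects(deg_genes, nw)
        over <- overconnected_set(objs, nw, config$connectivity_alpha)
        write_table(over, file.path(config$outdir, "overconnected.tsv"))
        list(dataset_objects = objs, over = over,
             topology = topology_summary(objs, nw))
      }
    })
    counts$overconnected <- if (is.null(conn)) 0L else nrow(conn$over)
    message("interactome: ", counts$overconnected,
            " over-connected objects")
  }

  hs <- stage("hotspot", {
    ordered <- order_genome(annotation)
    h <- scan_hotspots(ordered, deg_genes, config$hotspot_min_k,
                       config$hotspot_alpha)
    write_table(h, file.path(config$outdir, "hotspots.tsv"))
    write_hotspots_bed(h, file.path(config$outdir, "hotspots.bed"))
    if (nrow(h) == 0 && length(deg_genes) == 0)
      warning("no DEGs: hot-spot scan empty")
    list(ordered = ordered, hotspots = h,
         membership = hotspot_membership(h, degs$table))
  })
  counts$hotspots <- nrow(hs$hotspots)
  counts$degs_in_hotspots <- hs$membership$n_inside
  message("hotspot: ", counts$hotspots, " hot spots containing ",
          counts$degs_in_hotspots, " DEGs")

  manifest <- list(
    package = "degnet",
    version = as.character(utils::packageVersion("degnet")),
    seed = config$seed,
    parameters = config[c("cv_threshold", "deg_p_max", "deg_fc_min",
                          "enrich_alpha", "connectivity_alpha",
                          "hotspot_min_k", "hotspot_alpha")],
    excluded_samples = config$exclude_samples,
    counts = counts)
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(manifest, results = list(signature = sig, deg = degs,
                                     enrichment = enr, interactome = conn,
                                     hotspot = hs))
}

#' Compare a DEG list with a reference gene list
#'
#' Reports the intersection and, when directions are supplied for both
#' sides, per-gene direction concordance (e.g. a gene down in this dataset
#' but up in a published list counts as overlapping, non-concordant).
#'
#' @param deg_genes character vector of gene symbols, or a named vector /
#'   data.frame carrying directions.
#' @param reference_list character vector of reference symbols, or a named
#'   vector of directions.
#' @param deg_directions,reference_directions optional named vectors of
#'   directions (`"up"`/`"down"`, or signs) keyed by gene symbol.
#' @return list with `overlap` (character), `n_overlap`, and `concordance`
#'   (data.frame with per-gene direction agreement; `NULL` when directions
#'   are unavailable).
#' @export
compare_gene_lists <- function(deg_genes, reference_list,
                               deg_directions = NULL,
                               reference_directions = NULL) {
  norm_dir <- function(d) {
    if (is.null(d)) return(NULL)
    v <- tolower(as.character(d))
    v[v %in% c("1", "+1", "up", "uip")] <- "up"
    v[v %in% c("-1", "down", "dip")] <- "down"
    stats::setNames(v, names(d))
  }
  if (is.data.frame(deg_genes)) {
    deg_directions <- stats::setNames(deg_genes$direction,
                                      deg_genes$gene_symbol)
    deg_genes <- deg_genes$gene_symbol
  }
  dd <- norm_dir(deg_directions); rd <- norm_dir(reference_directions)
  overlap <- intersect(unique(deg_genes), unique(reference_list))
  concordance <- NULL
  if (!is.null(dd) && !is.null(rd) && length(overlap)) {
    concordance <- data.frame(
      gene_symbol = overlap,
      deg_direction = unname(dd[overlap]),
      reference_direction = unname(rd[overlap]),
      concordant = unname(dd[overlap] == rd[overlap]),
      stringsAsFactors = FALSE)
  }
  list(overlap = sort(overlap), n_overlap = length(overlap),
       concordance = concordance)
}

#' Published over-connectivity benchmark values
#'
#' A published visceral-leishmaniasis blood-transcriptome study reports,
#' for each of its significantly over-connected proteins, the observed
#' dataset-neighbor count `A`, dataset size `n`, background degree `R`
#' and background size `N` together with the derived `E`, connectivity
#' ratio, z-score and tail p-value. The table is shipped as a plain-text
#' fixture and is used to validate [connectivity_stats()] end to end: the
#' derived columns must be reproducible from `(A, n, R, N)` at printed
#' precision. The printed values truncate rather than round in places, so
#' comparisons should allow one unit in the last printed digit.
#'
#' @return data.frame with columns `object_name`, `gene_ids`,
#'   `fold_change`, `A`, `n`, `R`, `N`, `E`, `ratio`, `z`, `p`, and
#'   `p_tol` (one unit in the last printed digit of `p`).
#' @export
overconnectivity_benchmark <- function() {
  path <- system.file("extdata", "vl_blood_overconnectivity.tsv",
                      package = "degnet")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
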