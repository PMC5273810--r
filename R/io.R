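#' Read a probe-level expression matrix and its sample sheet
#'
#' The matrix file is tab-separated with a `probe_id` column followed by one
#' numeric column per sample (log2 intensities); the sample sheet is a CSV
#' with columns `sample,group` (`group` in case/control). Malformed input is
#' rejected with the offending row or column named, never coerced.
#'
#' @param path path to the expression TSV.
#' @param sample_sheet_path path to the sample sheet CSV.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, sample_sheet_path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (!file.exists(sample_sheet_path))
    stop("sample sheet not found: ", sample_sheet_path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (names(tab)[1] != "probe_id")
    stop("first column of ", path, " must be 'probe_id'")
  probe_ids <- tab$probe_id
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at probe '%s', sample '%s'",
                 probe_ids[bad[1]], colnames(vals)[bad[2]]))
  }
  rownames(num) <- probe_ids
  sheet <- utils::read.csv(sample_sheet_path, colClasses = "character")
  if (!all(c("sample", "group") %in% names(sheet)))
    stop("sample sheet must have columns 'sample' and 'group'")
  groups <- stats::setNames(sheet$group, sheet$sample)
  expr_matrix(num, groups)
}

#' Write an expression matrix and sample sheet
#'
#' Inverse of [read_expression()]. Values are written with 17 significant
#' digits, which round-trips IEEE doubles bit-exactly.
#'
#' @param x an `expr_matrix`.
#' @param path output TSV path.
#' @param sample_sheet_path output CSV path.
#' @export
write_expression <- function(x, path, sample_sheet_path) {
  df <- data.frame(probe_id = rownames(x$values),
                   apply(x$values, 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(sample = names(x$groups),
                              group = unname(x$groups)),
                   sample_sheet_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one term per line, tab-separated
#' `term_id<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer
#' than three fields, empty member lists or duplicate members within a term
#' are rejected with the line number.
#'
#' @param path GMT file path.
#' @return A `gene_sets` object: a named list of character member vectors
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    members <- f[-(1:2)]
    if (anyDuplicated(members))
      stop(sprintf("malformed GMT line %d: duplicate members", i))
    ids[i] <- f[1]; desc[i] <- f[2]; sets[[i]] <- members
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT")
  names(sets) <- ids
  structure(sets, descriptions = stats::setNames(desc, ids),
            class = "gene_sets")
}

#' Write a gene-set collection as GMT
#'
#' @param sets a `gene_sets` object (or named list of member vectors).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed signed interaction network and gene-object mapping
#'
#' Edge list TSV with columns `source,target,direction,sign` (direction is
#' kept for provenance; sign in -1/0/1) and a mapping TSV with columns
#' `gene,object` (many genes may map to one object). Self-loops are dropped
#' with a warning reporting how many. The background size `N` is the number
#' of distinct objects seen across edges, mapping and the optional
#' `objects_path` (one object id per line, for isolated background objects).
#'
#' @param edges_path edge-list TSV.
#' @param mapping_path gene-to-object TSV.
#' @param objects_path optional file listing all background object ids.
#' @return An `interaction_network`: list with `graph` (directed igraph with
#'   `sign` edge attribute), `gene_to_object` (named character vector),
#'   `objects` and `N`.
#' @export
read_network <- function(edges_path, mapping_path, objects_path = NULL) {
  if (!file.exists(edges_path)) stop("edge list not found: ", edges_path)
  if (!file.exists(mapping_path)) stop("mapping not found: ", mapping_path)
  ed <- utils::read.delim(edges_path, colClasses = "character")
  need <- c("source", "target", "direction", "sign")
  if (!all(need %in% names(ed)))
    stop("edge list must have columns ", paste(need, collapse = ", "))
  loops <- ed$source == ed$target
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped")
    ed <- ed[!loops, , drop = FALSE]
  }
  mp <- utils::read.delim(mapping_path, colClasses = "character")
  if (!all(c("gene", "object") %in% names(mp)))
    stop("mapping must have columns 'gene' and 'object'")
  objects <- unique(c(ed$source, ed$target, mp$object))
  if (!is.null(objects_path))
    objects <- unique(c(objects, readLines(objects_path)))
  interaction_network(edges = data.frame(source = ed$source,
                                         target = ed$target,
                                         sign = as.integer(ed$sign),
                                         stringsAsFactors = FALSE),
                      gene_to_object = stats::setNames(mp$object, mp$gene),
                      objects = objects)
}

#' Construct an interaction network container
#'
#' @param edges data.frame with columns `source`, `target`, `sign`.
#' @param gene_to_object named character vector (gene symbol -> object id).
#' @param objects character vector of all background object ids (defaults to
#'   the union of edge endpoints and mapped objects).
#' @return An `interaction_network` object.
#' @export
interaction_network <- function(edges, gene_to_object,
                                objects = NULL) {
  if (is.null(objects))
    objects <- unique(c(edges$source, edges$target, unname(gene_to_object)))
  stray <- setdiff(c(edges$source, edges$target), objects)
  if (length(stray)) stop("edge endpoints not among objects: ",
                          paste(utils::head(stray), collapse = ", "))
  if (any(edges$source == edges$target)) stop("self-loops not allowed")
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = objects))
  structure(list(graph = g, gene_to_object = gene_to_object,
                 objects = objects, N = length(objects)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: N = %d objects, %d directed edges, %d mapped genes\n",
              x$N, igraph::ecount(x$graph), length(x$gene_to_object)))
  invisible(x)
}

#' Write an interaction network (edge list + mapping + object list)
#'
#' @param network an `interaction_network`.
#' @param edges_path,mapping_path,objects_path output paths
#'   (`objects_path` optional; needed to round-trip isolated objects).
#' @export
write_network <- function(network, edges_path, mapping_path,
                          objects_path = NULL) {
  ed <- igraph::as_data_frame(network$graph, what = "edges")
  out <- data.frame(source = ed$from, target = ed$to,
                    direction = "->", sign = ed$sign)
  utils::write.table(out, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene = names(network$gene_to_object),
                                object = unname(network$gene_to_object)),
                     mapping_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(objects_path)) writeLines(network$objects, objects_path)
  invisible(edges_path)
}

#' Write hot spots as a BED track
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `bed_start = start_bp - 1` and `bed_end = end_bp`.
#'
#' @param hotspots data.frame as returned by [scan_hotspots()].
#' @param path output BED path.
#' @export
write_hotspots_bed <- function(hotspots, path) {
  if (nrow(hotspots) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(1000L, as.integer(round(-100 * log10(hotspots$p_value))))
  bed <- data.frame(chrom = hotspots$chromosome,
                    start = hotspots$start_bp - 1L,
                    end = hotspots$end_bp,
                    name = sprintf("hotspot_%d", seq_len(nrow(hotspots))),
                    score = score,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write or read a simulation truth record as JSON
#'
#' @param truth truth list from [simulate_study()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  truth$deg_genes <- as.list(truth$deg_genes)  # keep gene names in JSON
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$deg_genes <- unlist(tr$deg_genes)
  if (is.data.frame(tr$hotspot_intervals))
    tr$hotspot_intervals <- lapply(seq_len(nrow(tr$hotspot_intervals)),
                                   function(i) as.list(tr$hotspot_intervals[i, ]))
  tr
}

#' Write a result table as TSV
#'
#' @param records a data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
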