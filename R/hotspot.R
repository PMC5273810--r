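#' Order unique genes along the genome
#'
#' Collapses the probe annotation to one row per gene (the first-listed
#' probe's locus; duplicate probes are masked) and sorts genes within each
#' chromosome by transcript start, ties broken by gene symbol. Strand is
#' ignored: locus position, not orientation, defines a stretch. Probes
#' without a gene symbol or coordinates are dropped. A gene annotated on
#' two chromosomes keeps its first-listed locus, with a warning.
#'
#' @param annotation probe annotation data.frame.
#' @return data.frame ordered by (chromosome, start): `chromosome`,
#'   `gene_symbol`, `start`, `end`, with `index` (position within its
#'   chromosome).
#' @export
order_genome <- function(annotation) {
  validate_annotation(annotation)
  ann <- annotation[!is.na(annotation$gene_symbol) &
                      !is.na(annotation$chromosome) &
                      !is.na(annotation$start), , drop = FALSE]
  first <- ann[!duplicated(ann$gene_symbol), , drop = FALSE]
  n_chroms <- tapply(ann$chromosome, ann$gene_symbol,
                     function(ch) length(unique(ch)))
  conflicted <- names(n_chroms)[n_chroms > 1]
  if (length(conflicted))
    warning("gene(s) annotated on multiple chromosomes, first locus kept: ",
            paste(utils::head(conflicted, 5), collapse = ", "))
  ord <- order(first$chromosome, first$start, first$gene_symbol)
  out <- data.frame(chromosome = first$chromosome[ord],
                    gene_symbol = first$gene_symbol[ord],
                    start = first$start[ord], end = first$end[ord],
                    stringsAsFactors = FALSE)
  out$index <- stats::ave(seq_len(nrow(out)), out$chromosome,
                          FUN = seq_along)
  out
}

#' Scan ordered genes for DEG-dense chromosomal hot spots
#'
#' Every candidate stretch of consecutive genes delimited by DEG genes at
#' both ends and containing at least `min_k` DEGs among its `m` genes is
#' scored with an exact hypergeometric scan p-value,
#' `P(X >= k | m draws, D DEGs among G genes)`, against genome-wide totals
#' by default (`scope = "chromosome"` conditions on per-chromosome
#' totals). Stretches with `p <= alpha` are retained; overlapping or
#' adjacent significant stretches on a chromosome are merged into maximal
#' hot spots whose p-value is the minimum over the merged members (with
#' `m` and `k` recomputed for the merged span).
#'
#' @param ordered genome ordering from [order_genome()].
#' @param deg_genes character vector of DEG gene symbols.
#' @param min_k minimum DEG count per stretch (default 3).
#' @param alpha scan p-value cutoff (inclusive, default 0.05).
#' @param scope `"genome"` (default) or `"chromosome"` totals for the
#'   hypergeometric null.
#' @param adjust apply BH across candidate stretches before thresholding
#'   (off by default; the conventional scan reports unadjusted p).
#' @return data.frame of hot spots: `chromosome`, `start_bp`, `end_bp`
#'   (1-based inclusive), `start_index`, `end_index`, `m`, `k`,
#'   `p_value`, `source`, `genes` (comma-separated member genes).
#' @export
scan_hotspots <- function(ordered, deg_genes, min_k = 3, alpha = 0.05,
                          scope = c("genome", "chromosome"),
                          adjust = FALSE) {
  scope <- match.arg(scope)
  flags <- ordered$gene_symbol %in% deg_genes
  G_all <- nrow(ordered); D_all <- sum(flags)
  empty <- data.frame(chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0), start_index = integer(0),
                      end_index = integer(0), m = integer(0),
                      k = integer(0), p_value = numeric(0),
                      source = character(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (D_all == 0) return(empty)
  cand <- list()
  for (ch in unique(ordered$chromosome)) {
    rows <- which(ordered$chromosome == ch)
    f <- flags[rows]
    pos <- which(f)
    if (length(pos) < min_k) next
    G <- if (scope == "genome") G_all else length(rows)
    D <- if (scope == "genome") D_all else length(pos)
    for (i in seq_len(length(pos) - min_k + 1)) {
      for (j in seq(i + min_k - 1, length(pos))) {
        m <- pos[j] - pos[i] + 1L
        k <- j - i + 1L
        p <- stats::phyper(k - 1, D, G - D, m, lower.tail = FALSE)
        cand[[length(cand) + 1L]] <-
          data.frame(chromosome = ch, start_index = pos[i],
                     end_index = pos[j], m = m, k = k, p_value = p,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  pv <- if (adjust) stats::p.adjust(cand$p_value, "BH") else cand$p_value
  sig <- cand[pv <= alpha, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  merged <- merge_windows(sig)
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    w <- merged[i, ]
    rows <- which(ordered$chromosome == w$chromosome)
    span <- rows[w$start_index:w$end_index]
    genes <- ordered$gene_symbol[span]
    data.frame(chromosome = w$chromosome,
               start_bp = ordered$start[span[1]],
               end_bp = ordered$end[span[length(span)]],
               start_index = w$start_index, end_index = w$end_index,
               m = length(span), k = sum(genes %in% deg_genes),
               p_value = w$p_value, source = "analytic",
               genes = paste(genes, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out[order(out$chromosome, out$start_index), , drop = FALSE]
}

# merge overlapping/adjacent significant index windows per chromosome;
# merged p = min over members. Idempotent and order-independent.
merge_windows <- function(win) {
  out <- list()
  for (ch in unique(win$chromosome)) {
    w <- win[win$chromosome == ch, , drop = FALSE]
    w <- w[order(w$start_index, w$end_index), , drop = FALSE]
    cur <- w[1, ]
    for (i in seq_len(nrow(w))[-1]) {
      if (w$start_index[i] <= cur$end_index + 1L) {
        cur$end_index <- max(cur$end_index, w$end_index[i])
        cur$p_value <- min(cur$p_value, w$p_value[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- w[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

#' Permutation null for a hot-spot window
#'
#' Empirical p-value for one window: DEG labels are permuted uniformly
#' over all gene positions `B` times and the fraction of permutations
#' placing at least the observed number of DEGs inside the window's span
#' is reported with add-one continuity, `(1 + hits) / (B + 1)`.
#'
#' @param ordered genome ordering from [order_genome()].
#' @param deg_genes character vector of DEG gene symbols.
#' @param window one row of a [scan_hotspots()] result (or any list with
#'   `chromosome`, `start_index`, `end_index`).
#' @param B number of permutations (>= 100).
#' @param seed integer seed for reproducibility.
#' @return The empirical p-value.
#' @export
hotspot_permutation_p <- function(ordered, deg_genes, window, B = 10000,
                                  seed = 1L) {
  if (B < 100) stop("B must be >= 100")
  set.seed(seed)
  flags <- ordered$gene_symbol %in% deg_genes
  G <- nrow(ordered); D <- sum(flags)
  rows <- which(ordered$chromosome == window$chromosome)
  span <- rows[window$start_index:window$end_index]
  k_obs <- sum(flags[span])
  hits <- 0L
  for (b in seq_len(B)) {
    perm <- sample.int(G, D)
    if (sum(perm %in% span) >= k_obs) hits <- hits + 1L
  }
  (1 + hits) / (B + 1)
}

#' DEG membership of hot spots
#'
#' @param hotspots data.frame from [scan_hotspots()].
#' @param deg_records DEG table ([collapse_probes()]) or a character
#'   vector of DEG gene symbols.
#' @return list with `per_hotspot` (list of DEG vectors, one per hot
#'   spot), `inside` (DEGs in any hot spot), `outside` (remaining DEGs)
#'   and `n_inside`/`n_outside`.
#' @export
hotspot_membership <- function(hotspots, deg_records) {
  degs <- if (is.data.frame(deg_records)) deg_records$gene_symbol
          else deg_records
  per <- lapply(seq_len(nrow(hotspots)), function(i)
    intersect(strsplit(hotspots$genes[i], ",", fixed = TRUE)[[1]], degs))
  inside <- unique(unlist(per))
  outside <- setdiff(degs, inside)
  list(per_hotspot = per, inside = inside, outside = outside,
       n_inside = length(inside), n_outside = length(outside))
}
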