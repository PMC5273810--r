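#' Per-probe Welch differential expression between cases and controls
#'
#' Welch's two-sample t-test on log2 intensities for every probe, with the
#' signed linear fold change convention used throughout this package: the
#' ratio of anti-logged group means when >= 1 (up in patients), its negated
#' reciprocal when < 1 (down in patients), so |FC| >= 1 always and equal
#' means give +1. Benjamini-Hochberg q-values are reported alongside the
#' raw p-values but are not used for DEG selection.
#'
#' @param x an [expr_matrix()] with at least 2 samples per group.
#' @return data.frame with columns `probe_id`, `mean_case`, `mean_control`
#'   (linear scale, anti-logged group means), `signed_fc`, `t_stat`,
#'   `p_value`, `q_value`.
#' @export
test_differential <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  ca <- x$values[, x$groups == "case", drop = FALSE]
  co <- x$values[, x$groups == "control", drop = FALSE]
  n1 <- ncol(ca); n2 <- ncol(co)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(ca); m2 <- rowMeans(co)
  v1 <- rowSums((ca - m1)^2) / (n1 - 1)
  v2 <- rowSums((co - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  t_stat <- ifelse(se2 > 0, diff / sqrt(se2),
                   ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              ifelse(t_stat == 0, 1, 0))
  ratio <- 2^diff
  signed_fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  data.frame(probe_id = rownames(x$values),
             mean_case = 2^m1, mean_control = 2^m2,
             signed_fc = signed_fc, t_stat = t_stat,
             p_value = p, q_value = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Threshold differential statistics into a DEG probe list
#'
#' Keeps probes with `p_value < p_max` (strict) and `|signed_fc| >= fc_min`
#' (inclusive) — the conventional p < 0.05, |FC| >= 1.4 contract.
#'
#' @param stats data.frame from [test_differential()].
#' @param p_max p-value cutoff (exclusive).
#' @param fc_min absolute signed fold-change cutoff (inclusive).
#' @return The qualifying subset, original order preserved.
#' @export
select_degs <- function(stats, p_max = 0.05, fc_min = 1.4) {
  if (p_max <= 0 || fc_min <= 0) stop("thresholds must be positive")
  stats[stats$p_value < p_max & abs(stats$signed_fc) >= fc_min, ,
        drop = FALSE]
}

#' Collapse qualifying probes to one record per gene
#'
#' Trims unannotated probes and pseudogenes, then groups the remaining
#' probes by gene symbol and retains the representative probe with the
#' largest |signed FC|, breaking ties by lowest p-value and then by
#' lexicographic probe id. Direction is UIP (up in patients) for positive
#' FC and DIP (down in patients) for negative.
#'
#' @param selected data.frame of qualifying probes ([select_degs()]).
#' @param annotation probe annotation data.frame (see
#'   [simulate_expression()] for the column contract).
#' @return data.frame with one row per gene: `gene_symbol`,
#'   `representative_probe`, `signed_fc`, `p_value`, `direction`.
#' @export
collapse_probes <- function(selected, annotation) {
  validate_annotation(annotation)
  ann <- annotation[match(selected$probe_id, annotation$probe_id), ]
  keep <- !is.na(ann$gene_symbol) & !ann$pseudogene_flag
  sel <- selected[keep, , drop = FALSE]
  sel$gene_symbol <- ann$gene_symbol[keep]
  if (nrow(sel) == 0)
    return(data.frame(gene_symbol = character(0),
                      representative_probe = character(0),
                      signed_fc = numeric(0), p_value = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  ord <- order(sel$gene_symbol, -abs(sel$signed_fc), sel$p_value,
               sel$probe_id)
  sel <- sel[ord, ]
  rep_rows <- sel[!duplicated(sel$gene_symbol), ]
  data.frame(gene_symbol = rep_rows$gene_symbol,
             representative_probe = rep_rows$probe_id,
             signed_fc = rep_rows$signed_fc,
             p_value = rep_rows$p_value,
             direction = ifelse(rep_rows$signed_fc > 0, "UIP", "DIP"),
             stringsAsFactors = FALSE, row.names = NULL)
}
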