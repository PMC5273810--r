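#' Coefficient-of-variation probe filter
#'
#' Retains probes whose coefficient of variation (sample SD / mean) across
#' all arrays exceeds `threshold`. By default the CV is computed on the
#' linear intensity scale (stored values are log2, so they are anti-logged
#' first); `scale = "log"` computes it on the stored values directly.
#' Probe order is preserved, so the filter is idempotent.
#'
#' @param x an [expr_matrix()].
#' @param threshold non-negative CV cutoff (default 0.12, the conventional
#'   informative-probe setting for this design).
#' @param scale `"linear"` (default) or `"log"`.
#' @return The filtered [expr_matrix()].
#' @export
cv_filter <- function(x, threshold = 0.12, scale = c("linear", "log")) {
  stopifnot(inherits(x, "expr_matrix"))
  scale <- match.arg(scale)
  if (threshold < 0) stop("`threshold` must be non-negative")
  if (ncol(x$values) < 2) stop("CV filter needs at least 2 samples")
  v <- if (scale == "linear") 2^x$values else x$values
  m <- rowMeans(v)
  s <- sqrt(rowSums((v - m)^2) / (ncol(v) - 1))
  cv <- ifelse(m == 0, 0, s / abs(m))
  keep <- if (threshold == 0) rep(TRUE, nrow(v)) else cv > threshold
  expr_matrix(x$values[keep, , drop = FALSE], x$groups)
}

#' Two-way hierarchical clustering of samples or probes
#'
#' Agglomerative clustering with the distance/linkage combinations used for
#' unsupervised disease-state signatures: 1 - Pearson correlation (default)
#' or Euclidean distance, with centroid, average or complete linkage.
#' Items are ordered lexicographically by id before clustering so the merge
#' tree is invariant to input row/column order. When clustering samples,
#' probes are standardized (per-probe z-score) first by default.
#'
#' @param x an [expr_matrix()].
#' @param axis `"samples"` (columns) or `"probes"` (rows).
#' @param distance `"one_minus_pearson"` or `"euclidean"`.
#' @param linkage `"centroid"`, `"average"` or `"complete"`.
#' @param standardize scale each probe to zero mean / unit SD before
#'   computing sample distances (ignored for the probe axis; constant
#'   probes are left at zero). Default `TRUE` for samples.
#' @return A `cluster_result`: list with `axis`, `merge`, `height`,
#'   `order`, `labels` and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(x, axis = c("samples", "probes"),
                                 distance = c("one_minus_pearson", "euclidean"),
                                 linkage = c("centroid", "average", "complete"),
                                 standardize = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  axis <- match.arg(axis); distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (is.null(standardize)) standardize <- axis == "samples"
  v <- x$values
  if (axis == "samples" && standardize) {
    m <- rowMeans(v); s <- apply(v, 1, stats::sd)
    s[s == 0] <- 1
    v <- (v - m) / s
  }
  mat <- if (axis == "samples") t(v) else v
  if (nrow(mat) < 2) stop("need at least 2 items to cluster")
  mat <- mat[order(rownames(mat)), , drop = FALSE]  # id-based tie stability
  d <- switch(distance,
              euclidean = stats::dist(mat),
              one_minus_pearson = stats::as.dist(1 - stats::cor(t(mat))))
  # R's centroid linkage expects squared distances; heights are reported
  # on the original scale
  h <- if (linkage == "centroid") {
    hh <- stats::hclust(d^2, method = "centroid")
    hh$height <- sqrt(pmax(hh$height, 0))
    hh
  } else stats::hclust(d, method = linkage)
  structure(list(axis = axis, merge = h$merge, height = h$height,
                 order = h$order, labels = h$labels, hclust = h),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d %s, %d merges\n",
              length(x$labels), x$axis, nrow(x$merge)))
  invisible(x)
}

#' Principal components analysis of samples
#'
#' Probes are centered (and optionally standardized) before the
#' decomposition; samples are projected onto the leading components.
#' Variance fractions are reported over all components, so they sum to 1
#' when `k` equals the matrix rank.
#'
#' @param x an [expr_matrix()].
#' @param k number of components to return scores for (default 3).
#' @param standardize scale probes to unit variance (default `FALSE`,
#'   i.e. covariance PCA).
#' @return A `pca_result`: list with `scores` (samples x k),
#'   `variance_fraction` (all components, non-increasing) and `k`.
#' @export
pca_samples <- function(x, k = 3, standardize = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2) stop("PCA needs at least 2 samples")
  v <- x$values
  if (standardize) {
    s <- apply(v, 1, stats::sd)
    drop <- s == 0
    if (any(drop)) {
      warning(sum(drop), " constant probe(s) dropped before standardized PCA")
      v <- v[!drop, , drop = FALSE]
    }
  }
  if (nrow(v) == 0 || all(apply(v, 1, stats::sd) == 0)) {
    warning("constant matrix: all variance fractions are 0")
    k_eff <- min(k, ncol(x$values))
    scores <- matrix(0, ncol(x$values), k_eff,
                     dimnames = list(colnames(x$values),
                                     paste0("PC", seq_len(k_eff))))
    return(structure(list(scores = scores,
                          variance_fraction = rep(0, k_eff), k = k_eff),
                     class = "pca_result"))
  }
  pc <- stats::prcomp(t(v), center = TRUE, scale. = standardize)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k_eff <- min(k, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(k_eff), drop = FALSE],
                 variance_fraction = vf, k = k_eff),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, top-%d variance fractions: %s\n",
              nrow(x$scores), x$k,
              paste(sprintf("%.1f%%",
                            100 * x$variance_fraction[seq_len(x$k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Compare a 2-cut of the sample dendrogram with the group labels
#'
#' Cuts the sample tree into two clusters and reports the adjusted Rand
#' index against the case/control assignment — the unsupervised
#' disease-state separation check.
#'
#' @param cl a `cluster_result` for the sample axis.
#' @param groups named group vector (as in `expr_matrix$groups`).
#' @return The adjusted Rand index (1 = perfect separation).
#' @export
signature_separation <- function(cl, groups) {
  stopifnot(inherits(cl, "cluster_result"), cl$axis == "samples")
  cut2 <- stats::cutree(cl$hclust, k = 2)
  adjusted_rand_index(cut2, groups[names(cut2)])
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
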