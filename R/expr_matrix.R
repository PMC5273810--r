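#' Probe-level expression matrix with group labels
#'
#' Container for a probes x samples matrix of log2 intensities together with
#' a case/control assignment for every sample. This is the object every
#' downstream stage (variance filtering, clustering, differential testing)
#' consumes.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids), log2 intensity units.
#' @param groups named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (named character vector aligned to the
#'   columns).
#' @export
expr_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  pid <- rownames(values); sid <- colnames(values)
  if (is.null(pid) && nrow(values) == 0) pid <- character(0)
  if (is.null(pid) || is.null(sid))
    stop("`values` must have probe rownames and sample colnames")
  if (anyDuplicated(pid))
    stop("duplicate probe ids: ", paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at probe '%s', sample '%s'",
                 pid[bad[1]], sid[bad[2]]))
  }
  missing <- setdiff(sid, names(groups))
  if (length(missing))
    stop("samples without a group assignment: ", paste(missing, collapse = ", "))
  groups <- groups[sid]
  if (!all(groups %in% c("case", "control")))
    stop("groups must be 'case' or 'control'")
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by probe and/or sample ids
#'
#' @param x an `expr_matrix`.
#' @param probes,samples character vectors of ids to retain (default: all).
#'   Order of the retained ids follows the original matrix.
#' @return An `expr_matrix` restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, probes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(probes))  v <- v[rownames(v) %in% probes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, colnames(v) %in% samples, drop = FALSE]
  expr_matrix(v, x$groups)
}

# shared column checker for annotation tables
validate_annotation <- function(annotation) {
  need <- c("probe_id", "gene_symbol", "chromosome", "start", "end",
            "strand", "pseudogene_flag")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  has_coord <- !is.na(annotation$start) & !is.na(annotation$end)
  if (any(has_coord & annotation$start > annotation$end))
    stop("annotation rows with start > end")
  if (any(has_coord & (is.na(annotation$chromosome) | annotation$chromosome == "")))
    stop("annotation rows with coordinates but empty chromosome")
  invisible(annotation)
}
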