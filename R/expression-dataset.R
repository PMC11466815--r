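#' Expression dataset with raw and normalized layers
#'
#' Container for a cells-by-genes experiment: nonnegative integer raw counts,
#' a variance-stabilized layer `normalized = log(1 + alpha * x_tilde)` where
#' `x_tilde` is the row-sum-normalized count matrix and `alpha` a positive
#' scale factor, a condition label per cell, and optional 2-D spatial
#' coordinates and region annotations.
#'
#' @param counts Nonnegative integer matrix, cells x genes, with dimnames.
#' @param condition Character/factor vector of per-cell condition labels.
#' @param coords Optional numeric matrix (cells x 2) of spatial coordinates.
#' @param region Optional per-cell region annotation.
#' @param alpha Positive scale factor; defaults to the median per-cell total
#'   count (recorded on the object and reused for the module log-transform).
#' @param normalized Optional precomputed normalized layer; computed from
#'   `counts` and `alpha` when absent.
#' @return An `expression_dataset` object.
#' @export
expression_dataset <- function(counts, condition, coords = NULL, region = NULL,
                               alpha = NULL, normalized = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    abort("`counts` must be nonnegative integers without missing values")
  if (length(condition) != nrow(counts))
    abort("`condition` must have one label per cell")
  if (anyNA(condition)) abort("missing condition label(s)")
  condition <- as.character(condition)
  if (is.null(alpha)) alpha <- median(rowSums(counts))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    abort("`alpha` must be a positive scalar")
  if (is.null(normalized)) normalized <- normalize_counts(counts, alpha)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nrow(counts) || ncol(coords) != 2)
      abort("`coords` must be a cells x 2 matrix")
    rownames(coords) <- rownames(counts)
  }
  if (!is.null(region) && length(region) != nrow(counts))
    abort("`region` must have one label per cell")
  structure(
    list(cell_ids = rownames(counts), gene_ids = colnames(counts),
         counts = counts, normalized = normalized, alpha = alpha,
         condition = condition, coords = coords,
         region = if (is.null(region)) NULL else as.character(region),
         spatial = !is.null(coords)),
    class = "expression_dataset"
  )
}

# log(1 + alpha * row-normalized counts); all-zero cells stay zero.
normalize_counts <- function(counts, alpha) {
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  log1p(alpha * counts / tot)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d cells x %d genes, alpha = %.4g%s\n",
              length(x$cell_ids), length(x$gene_ids), x$alpha,
              if (x$spatial) ", spatial" else ""))
  cat("  conditions:", paste(unique(x$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize an expression dataset
#'
#' @param x An `expression_dataset`.
#' @param ... Unused.
#' @return A one-row tibble of dimensions, scale factor and condition count.
#' @export
glance.expression_dataset <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$cell_ids), n_genes = length(x$gene_ids),
    alpha = x$alpha, n_conditions = length(unique(x$condition)),
    spatial = x$spatial
  )
}
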