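# Readers and writers for the external formats the pipeline touches: 10x-style
# MTX directories, dense CSV expression, per-spot communication score tables,
# factor matrices, and flow networks as TSV or GraphML.

#' Read an expression dataset from disk
#'
#' `format = "mtx_dir"` expects a directory with `matrix.mtx` (genes x cells,
#' 1-based indices per the Matrix Market standard), `features.tsv` and
#' `barcodes.tsv`, plus a `metadata.csv` (or `meta` argument) carrying the
#' condition column. `format = "csv"` expects a dense table whose first column
#' is the cell id and whose remaining header names are gene ids, with the
#' condition (and optional coordinate) columns alongside or in `meta`.
#'
#' @param path Directory (mtx_dir) or CSV file.
#' @param format `"mtx_dir"` or `"csv"`.
#' @param condition_column Name of the per-cell condition column.
#' @param coords_columns Optional length-2 names of coordinate columns.
#' @param meta Optional data frame of per-cell metadata (cell id in the first
#'   column) overriding any `metadata.csv`.
#' @param alpha Optional scale factor forwarded to [expression_dataset()].
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, format = c("mtx_dir", "csv"),
                            condition_column = "condition",
                            coords_columns = NULL, meta = NULL, alpha = NULL) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    feats <- readr::read_tsv(file.path(path, "features.tsv"),
                             col_names = FALSE, show_col_types = FALSE)
    bars <- readr::read_tsv(file.path(path, "barcodes.tsv"),
                            col_names = FALSE, show_col_types = FALSE)
    counts <- t(as.matrix(m))
    dimnames(counts) <- list(bars[[1]], feats[[1]])
    if (is.null(meta)) {
      mpath <- file.path(path, "metadata.csv")
      if (!file.exists(mpath)) abort("mtx_dir requires metadata.csv or `meta`")
      meta <- readr::read_csv(mpath, show_col_types = FALSE)
    }
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    cell_ids <- as.character(df[[1]])
    meta_cols <- intersect(c(condition_column, coords_columns), names(df))
    if (is.null(meta)) {
      meta <- dplyr::bind_cols(tibble::tibble(cell_id = cell_ids),
                               df[meta_cols])
    }
    gene_cols <- setdiff(names(df)[-1], meta_cols)
    counts <- as.matrix(df[gene_cols])
    rownames(counts) <- cell_ids
  }
  if (anyNA(counts) || any(counts < 0))
    abort("counts contain negative or missing entries")
  meta <- as.data.frame(meta)
  mrow <- match(rownames(counts), meta[[1]])
  if (anyNA(mrow)) abort("metadata does not cover every cell")
  if (!condition_column %in% names(meta))
    abort(sprintf("condition column '%s' not found", condition_column))
  condition <- meta[[condition_column]][mrow]
  coords <- NULL
  if (!is.null(coords_columns)) {
    if (!all(coords_columns %in% names(meta)))
      abort("coordinate column(s) not found")
    coords <- as.matrix(meta[mrow, coords_columns])
  }
  expression_dataset(counts, condition, coords = coords, alpha = alpha)
}

#' Write an expression dataset
#'
#' Inverse of [read_expression()]: either an MTX directory (counts transposed
#' to genes x cells, plus features/barcodes/metadata) or a dense CSV with the
#' metadata columns alongside.
#'
#' @param dataset An [expression_dataset()].
#' @param path Target directory (mtx_dir) or CSV file.
#' @inheritParams read_expression
#' @export
write_expression <- function(dataset, path, format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  meta <- tibble::tibble(cell_id = dataset$cell_ids,
                         condition = dataset$condition)
  if (dataset$spatial) {
    meta$x <- dataset$coords[, 1]; meta$y <- dataset$coords[, 2]
  }
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(dataset$counts), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble::tibble(x = dataset$gene_ids),
                     file.path(path, "features.tsv"), col_names = FALSE)
    readr::write_tsv(tibble::tibble(x = dataset$cell_ids),
                     file.path(path, "barcodes.tsv"), col_names = FALSE)
    readr::write_csv(meta, file.path(path, "metadata.csv"))
  } else {
    df <- dplyr::bind_cols(
      tibble::tibble(cell_id = dataset$cell_ids),
      tibble::as_tibble(dataset$counts),
      meta[-1]
    )
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Read a per-spot received-signal score table
#'
#' A CSV whose first column is the spot id and whose remaining columns are
#' canonical interaction names (`L1+L2->R1+R2`); entries are nonnegative
#' communication scores.
#'
#' @param path CSV file.
#' @return A `spatial_scores` object: list with `spot_ids`, `interactions`,
#'   and the `scores` matrix.
#' @export
read_scores <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  scores <- as.matrix(df[-1])
  rownames(scores) <- as.character(df[[1]])
  spatial_scores(scores)
}

#' @rdname read_scores
#' @param scores Nonnegative spots-by-interactions matrix with dimnames.
#' @export
spatial_scores <- function(scores) {
  if (anyNA(scores) || any(scores < 0))
    abort("communication scores must be nonnegative")
  structure(
    list(spot_ids = rownames(scores), interactions = colnames(scores),
         scores = scores),
    class = "spatial_scores"
  )
}

#' Read or construct a gene-expression-module factorization
#'
#' @param membership Nonnegative cells-by-K membership matrix (columns
#'   `GEM-1..K`), or a CSV path whose first column is the cell id.
#' @param loadings Nonnegative genes-by-K shared loadings matrix, or a CSV
#'   path whose first column is the gene id.
#' @param condition_loadings Optional named list of per-condition
#'   genes-by-K loading matrices.
#' @return A `gem_factorization` object.
#' @export
gem_factorization <- function(membership, loadings = NULL,
                              condition_loadings = NULL) {
  read_mat <- function(x) {
    if (is.character(x)) {
      df <- readr::read_csv(x, show_col_types = FALSE)
      m <- as.matrix(df[-1]); rownames(m) <- as.character(df[[1]]); m
    } else as.matrix(x)
  }
  membership <- read_mat(membership)
  if (anyNA(membership) || any(membership < 0))
    abort("membership matrix must be nonnegative")
  K <- ncol(membership)
  if (is.null(colnames(membership)))
    colnames(membership) <- paste0("GEM-", seq_len(K))
  if (!is.null(loadings)) {
    loadings <- read_mat(loadings)
    if (any(loadings < 0)) abort("loadings must be nonnegative")
    if (ncol(loadings) != K) abort("loadings and membership disagree on K")
    colnames(loadings) <- colnames(membership)
  }
  if (!is.null(condition_loadings)) {
    condition_loadings <- lapply(condition_loadings, read_mat)
    if (any(vapply(condition_loadings, ncol, 1L) != K))
      abort("condition loadings disagree on K")
    if (any(unlist(lapply(condition_loadings, min)) < 0))
      abort("condition loadings must be nonnegative")
  }
  structure(
    list(membership = membership, shared_loadings = loadings,
         condition_loadings = condition_loadings, K = K),
    class = "gem_factorization"
  )
}

#' Write a flow network to TSV or GraphML
#'
#' TSV columns are `source`, `target`, `source_class`, `target_class`,
#' `weight`, sorted lexicographically by (source, target); GraphML carries the
#' same attributes. Refuses to serialize a network whose arcs violate the
#' biological flow model.
#'
#' @param network A [flow_network()].
#' @param path Output file.
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  check_flow_arcs(network)
  tb <- tidy(network)
  if (format == "tsv") {
    readr::write_tsv(tb, path)
  } else {
    g <- igraph::graph_from_data_frame(
      tb[c("source", "target", "weight", "source_class", "target_class")],
      directed = TRUE,
      vertices = tibble::tibble(name = network$nodes,
                                var_class = unname(network$var_class))
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a flow network written by [write_network()]
#'
#' @param path File produced by [write_network()].
#' @inheritParams write_network
#' @return A [flow_network()].
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tb <- readr::read_tsv(path, show_col_types = FALSE)
    cls <- c(setNames(tb$source_class, tb$source),
             setNames(tb$target_class, tb$target))
    cls <- cls[!duplicated(names(cls))]
    flow_network(arcs = tb[c("source", "target", "weight")],
                 var_class = cls)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    vt <- igraph::as_data_frame(g, what = "vertices")
    flow_network(
      arcs = tibble::tibble(source = el$from, target = el$to,
                            weight = el$weight),
      var_class = setNames(vt$var_class, vt$name)
    )
  }
}
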