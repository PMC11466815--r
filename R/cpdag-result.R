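#' Partially directed graph returned by structure learning
#'
#' Wraps a partially directed adjacency matrix: `amat[i, j]` alone encodes the
#' arc i -> j; `amat[i, j]` together with `amat[j, i]` encodes an undirected
#' edge. May carry a bootstrap-averaged adjacency (entries in `[0, 1]`) and,
#' for interventional learning, the estimated intervention targets of each
#' perturbed condition.
#'
#' @param amat Logical adjacency matrix with dimnames.
#' @param targets Optional named list of character vectors: estimated
#'   intervention targets per perturbed condition.
#' @param averaged Optional numeric matrix, the bootstrap-averaged adjacency.
#' @return An object of class `cpdag_result`.
#' @export
cpdag_result <- function(amat, targets = NULL, averaged = NULL) {
  stopifnot(is.matrix(amat), nrow(amat) == ncol(amat))
  if (is.null(dimnames(amat))) {
    nm <- paste0("V", seq_len(ncol(amat)))
    dimnames(amat) <- list(nm, nm)
  }
  diag(amat) <- FALSE
  if (!is.null(averaged)) {
    stopifnot(all(averaged >= 0), all(averaged <= 1))
    dimnames(averaged) <- dimnames(amat)
  }
  structure(
    list(nodes = colnames(amat), amat = amat, targets = targets,
         averaged = averaged),
    class = "cpdag_result"
  )
}

cpdag_arcs_und <- function(x) {
  a <- x$amat
  dir <- which(a & !t(a), arr.ind = TRUE)
  und <- which(a & t(a) & upper.tri(a), arr.ind = TRUE)
  list(
    arcs = cbind(from = x$nodes[dir[, 1]], to = x$nodes[dir[, 2]]),
    undirected = cbind(a = x$nodes[und[, 1]], b = x$nodes[und[, 2]])
  )
}

#' @export
print.cpdag_result <- function(x, ...) {
  e <- cpdag_arcs_und(x)
  cat(sprintf("<cpdag_result> %d nodes, %d arcs, %d undirected edges\n",
              length(x$nodes), nrow(e$arcs), nrow(e$undirected)))
  if (!is.null(x$targets)) {
    for (k in seq_along(x$targets)) {
      cat(sprintf("  targets[%s]: %s\n", names(x$targets)[k] %||% k,
                  paste(x$targets[[k]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Tidy a learned CPDAG into an edge table
#'
#' One row per edge with `from`, `to`, `directed`, and (when a bootstrap
#' average is present) the total edge `support`.
#'
#' @param x A `cpdag_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cpdag_result <- function(x, ...) {
  e <- cpdag_arcs_und(x)
  avg <- x$averaged
  wt <- function(i, j) if (is.null(avg)) NA_real_ else avg[i, j]
  dir_tb <- tibble::tibble(
    from = e$arcs[, "from"], to = e$arcs[, "to"], directed = TRUE
  )
  und_tb <- tibble::tibble(
    from = e$undirected[, "a"], to = e$undirected[, "b"], directed = FALSE
  )
  out <- dplyr::bind_rows(dir_tb, und_tb)
  if (!is.null(avg) && nrow(out)) {
    out$support <- avg[cbind(out$from, out$to)] + avg[cbind(out$to, out$from)]
  }
  dplyr::arrange(out, .data$from, .data$to)
}

#' Export a CPDAG adjacency as CSV
#'
#' Writes the partially directed adjacency matrix with a legend row
#' distinguishing directed arcs (2) from undirected edges (1).
#'
#' @param x A `cpdag_result`.
#' @param path Output file.
#' @export
write_cpdag_csv <- function(x, path) {
  a <- x$amat
  code <- matrix(0L, nrow(a), ncol(a), dimnames = dimnames(a))
  code[a & !t(a)] <- 2L
  code[a & t(a)] <- 1L
  df <- tibble::as_tibble(as.data.frame(code), rownames = "node")
  hdr <- "# legend: 2 = directed arc row->col, 1 = undirected edge, 0 = none"
  writeLines(hdr, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
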