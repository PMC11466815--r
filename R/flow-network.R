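#' Directed intercellular flow network
#'
#' Final, biologically oriented network: every arc runs inflow -> module,
#' module -> module, or module -> outflow, with positive weights (bootstrap
#' support in `[0, 2]` when aggregated).
#'
#' @param arcs Tibble/data frame with columns `source`, `target`, `weight`.
#' @param var_class Named character vector classing every node (`inflow`,
#'   `module`, `outflow`; `auxiliary` nodes may be present but carry no arcs).
#' @param provenance Optional list of learner settings recorded on the object.
#' @return A `flow_network` object.
#' @export
flow_network <- function(arcs, var_class, provenance = list()) {
  arcs <- tibble::as_tibble(arcs)
  if (!all(c("source", "target", "weight") %in% names(arcs)))
    abort("`arcs` needs columns source, target, weight")
  nodes <- sort(unique(c(names(var_class), arcs$source, arcs$target)))
  unclassed <- setdiff(nodes, names(var_class))
  if (length(unclassed))
    abort(paste0("unclassed node(s): ", paste(unclassed, collapse = ", ")))
  x <- structure(
    list(nodes = names(var_class), var_class = var_class,
         arcs = dplyr::arrange(arcs, .data$source, .data$target),
         provenance = provenance),
    class = "flow_network"
  )
  check_flow_arcs(x)
  x
}

check_flow_arcs <- function(x) {
  if (!nrow(x$arcs)) return(invisible(x))
  sc <- x$var_class[x$arcs$source]
  tc <- x$var_class[x$arcs$target]
  ok <- (sc == "inflow" & tc == "module") |
    (sc == "module" & tc == "module") |
    (sc == "module" & tc == "outflow")
  if (any(!ok)) {
    bad <- paste0(x$arcs$source[!ok], " -> ", x$arcs$target[!ok])
    abort(paste0("arc(s) violate the flow model: ",
                 paste(head(bad, 5), collapse = "; ")))
  }
  if (any(x$arcs$weight <= 0)) abort("arc weights must be positive")
  invisible(x)
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("<flow_network> %d nodes, %d arcs\n",
              length(x$nodes), nrow(x$arcs)))
  print(glance(x))
  invisible(x)
}

#' Tidy a flow network into an arc table
#'
#' One row per arc with source/target classes and bootstrap weight.
#'
#' @param x A `flow_network`.
#' @param ... Unused.
#' @return A tibble sorted by (source, target).
#' @export
tidy.flow_network <- function(x, ...) {
  tibble::tibble(
    source = x$arcs$source, target = x$arcs$target,
    source_class = unname(x$var_class[x$arcs$source]),
    target_class = unname(x$var_class[x$arcs$target]),
    weight = x$arcs$weight
  ) |>
    dplyr::arrange(.data$source, .data$target)
}

#' Summarize a flow network
#'
#' Node counts by class, arc count and total bootstrap weight.
#'
#' @param x A `flow_network`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.flow_network <- function(x, ...) {
  vc <- x$var_class
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_inflow = sum(vc == "inflow"), n_module = sum(vc == "module"),
    n_outflow = sum(vc == "outflow"), n_arcs = nrow(x$arcs),
    total_weight = sum(x$arcs$weight)
  )
}

#' Plot a flow network
#'
#' Layered ggplot2 rendering: inflows on the left, modules in the middle,
#' outflows on the right; edge width maps bootstrap support.
#'
#' @param object A `flow_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_network <- function(object, ...) {
  vc <- object$var_class
  lay <- tibble::tibble(
    node = names(vc), class = unname(vc),
    x = c(inflow = 0, module = 1, outflow = 2, auxiliary = 1)[unname(vc)]
  ) |>
    dplyr::group_by(.data$x) |>
    dplyr::mutate(y = seq_along(.data$node) - (dplyr::n() + 1) / 2) |>
    dplyr::ungroup()
  seg <- tidy(object) |>
    dplyr::left_join(lay, by = c(source = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(lay, by = c(target = "node")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$weight),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.6
    ) +
    ggplot2::geom_label(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node,
                   fill = .data$class), size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), limits = c(0, 2)) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "class", linewidth = "support")
}
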