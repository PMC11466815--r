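# From learned CPDAGs to the final intercellular flow network: bootstrap
# aggregation over resampled cells (or spatial blocks), removal of
# low-confidence edges, and biological flow-model orientation.

#' Bootstrap-aggregated structure learning
#'
#' Repeats the learner on resampled data `B` times, records each realization's
#' binary adjacency (arcs as directed entries, undirected edges as symmetric
#' entries) and returns the elementwise average adjacency together with the
#' CPDAG learned on the full data. A failing realization is redrawn once
#' before aborting.
#'
#' @param flowframe A [flow_frame()] (or plain matrix plus `condition`).
#' @param learner Function `(data_matrix, seed)` returning a [cpdag_result()];
#'   see [learner_gsp()] / [learner_ut_igsp()] for ready-made wrappers.
#' @param B Number of bootstrap realizations (default 100).
#' @param resampler Function `(flowframe, seed)` returning row indices;
#'   defaults to [resample_cells()] (condition-stratified). Pass
#'   `resampler = identity_resampler` to disable resampling.
#' @param seed Integer seed; realization b uses `seed + b`.
#' @return A [cpdag_result()] carrying the averaged adjacency.
#' @export
bootstrap_learn <- function(flowframe, learner, B = 100,
                            resampler = resample_cells, seed = 1) {
  stopifnot(B >= 1)
  vals <- if (inherits(flowframe, "flow_frame")) flow_values(flowframe)
          else as.matrix(flowframe)
  acc <- NULL
  for (b in seq_len(B)) {
    res <- NULL
    for (attempt in 1:2) {
      idx <- resampler(flowframe, seed = seed + b + (attempt - 1L) * 1000003L)
      res <- tryCatch(learner(vals[idx, , drop = FALSE],
                              cond = flowframe$condition[idx],
                              seed = seed + b),
                      error = function(e) e)
      if (!inherits(res, "error")) break
    }
    if (inherits(res, "error"))
      abort(paste0("learner failed twice on realization ", b, ": ",
                   conditionMessage(res)))
    acc <- if (is.null(acc)) res$amat + 0 else acc + res$amat
  }
  avg <- acc / B
  full <- learner(vals, cond = flowframe$condition, seed = seed)
  cpdag_result(full$amat, targets = full$targets, averaged = avg)
}

#' Condition-stratified bootstrap resampler
#'
#' Resamples cells with replacement within each condition, preserving the
#' per-condition sample sizes exactly.
#'
#' @param flowframe A [flow_frame()].
#' @param seed Integer seed.
#' @return Integer row indices (a multiset of `1..n`).
#' @export
resample_cells <- function(flowframe, seed = NULL) {
  cond <- if (inherits(flowframe, "flow_frame") ||
              is.data.frame(flowframe)) flowframe$condition
          else rep("all", nrow(flowframe))
  with_seed(seed, {
    unlist(lapply(split(seq_along(cond), cond), function(ix) {
      sample(ix, length(ix), replace = TRUE)
    }), use.names = FALSE)
  })
}

#' @rdname resample_cells
#' @export
identity_resampler <- function(flowframe, seed = NULL) {
  n <- if (is.data.frame(flowframe)) nrow(flowframe) else nrow(as.matrix(flowframe))
  seq_len(n)
}

#' Spatial block-bootstrap resampler
#'
#' Divides the tissue into non-overlapping blocks — k-means on the spatial
#' coordinates, graph (Leiden-style) clustering of the spatial connectivity
#' graph, or predefined region annotations — and resamples spots with
#' replacement within each block, preserving block sizes. Respects the spatial
#' correlation that plain resampling would destroy.
#'
#' @param dataset A spatial [expression_dataset()].
#' @param method `"kmeans"`, `"graph_cluster"` or `"annotation"`.
#' @param n_blocks Number of blocks for kmeans/graph clustering (default 20).
#' @param seed Integer seed.
#' @return Integer row indices, and the block assignment as attribute
#'   `"blocks"`.
#' @export
resample_spatial_blocks <- function(dataset,
                                    method = c("kmeans", "graph_cluster",
                                               "annotation"),
                                    n_blocks = 20, seed = NULL) {
  method <- match.arg(method)
  n <- length(dataset$cell_ids)
  if (method != "annotation" && n_blocks > n)
    abort("n_blocks exceeds the number of spots")
  blocks <- switch(method,
    kmeans = {
      if (!dataset$spatial) abort("kmeans blocks require coordinates")
      with_seed(seed, kmeans(dataset$coords, centers = n_blocks,
                             nstart = 5)$cluster)
    },
    graph_cluster = {
      if (!dataset$spatial) abort("graph blocks require coordinates")
      g <- build_spatial_graph(dataset, method = "knn", k = 6)
      ig <- igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                                weighted = TRUE)
      cl <- with_seed(seed, igraph::cluster_leiden(
        ig, objective_function = "modularity",
        n_iterations = 3))
      igraph::membership(cl)
    },
    annotation = {
      if (is.null(dataset$region)) abort("annotation blocks require `region`")
      as.integer(factor(dataset$region))
    }
  )
  idx <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    unlist(lapply(split(seq_len(n), blocks), function(ix) {
      sample(ix, length(ix), replace = TRUE)
    }), use.names = FALSE)
  })
  structure(idx, blocks = blocks)
}

#' Remove low-confidence edges from a bootstrap-averaged CPDAG
#'
#' For every skeleton edge, the total edge weight is
#' `w(i, j) = A_ij + A_ji` on the averaged adjacency; edges with
#' `w(i, j) < w_star` are zeroed in both directions.
#'
#' @param cpdag A [cpdag_result()] with an averaged adjacency.
#' @param w_star Threshold in (0, 1) (default 0.3).
#' @return The filtered [cpdag_result()].
#' @export
filter_low_confidence <- function(cpdag, w_star = 0.3) {
  if (w_star >= 1 || w_star <= 0) abort("`w_star` must lie in (0, 1)")
  avg <- cpdag$averaged
  if (is.null(avg)) abort("cpdag carries no averaged adjacency")
  w <- avg + t(avg)
  drop <- w < w_star
  amat <- cpdag$amat & !drop
  avg[drop] <- 0
  cpdag_result(amat, targets = cpdag$targets, averaged = avg)
}

#' Orient a CPDAG under the biological flow model
#'
#' Keeps only arcs directed inflow -> module, module -> module or
#' module -> outflow. Undirected inflow-module edges become inflow -> module,
#' module-outflow edges become module -> outflow, and module-module edges
#' contribute both directions; all other edges (including any touching
#' auxiliary nodes) are dropped. Arc weight is the total edge weight
#' `w(i, j)` of the underlying skeleton edge when a bootstrap average is
#' present, else 1.
#'
#' @param cpdag A [cpdag_result()].
#' @param var_classes Named character vector classing every node.
#' @param provenance Optional provenance list stored on the result.
#' @return A [flow_network()].
#' @export
apply_flow_model <- function(cpdag, var_classes, provenance = list()) {
  nodes <- cpdag$nodes
  unclassed <- setdiff(nodes, names(var_classes))
  if (length(unclassed))
    abort(paste0("unclassed node(s): ", paste(unclassed, collapse = ", ")))
  cls <- var_classes[nodes]
  a <- cpdag$amat
  wmat <- if (!is.null(cpdag$averaged)) cpdag$averaged + t(cpdag$averaged)
          else (skeleton_of(a)) * 1
  ok_arc <- function(s, t) {
    (cls[s] == "inflow" & cls[t] == "module") |
      (cls[s] == "module" & cls[t] == "module") |
      (cls[s] == "module" & cls[t] == "outflow")
  }
  arcs <- NULL
  dir <- which(a & !t(a), arr.ind = TRUE)
  if (nrow(dir)) {
    keep <- ok_arc(dir[, 1], dir[, 2])
    dir <- dir[keep, , drop = FALSE]
    arcs <- tibble::tibble(source = nodes[dir[, 1]], target = nodes[dir[, 2]],
                           weight = wmat[dir])
  }
  und <- which(a & t(a) & upper.tri(a), arr.ind = TRUE)
  if (nrow(und)) {
    for (r in seq_len(nrow(und))) {
      i <- und[r, 1]; j <- und[r, 2]
      w <- wmat[i, j]
      add <- NULL
      if (ok_arc(i, j) && ok_arc(j, i)) {        # module -- module
        add <- tibble::tibble(source = nodes[c(i, j)], target = nodes[c(j, i)],
                              weight = w)
      } else if (ok_arc(i, j)) {
        add <- tibble::tibble(source = nodes[i], target = nodes[j], weight = w)
      } else if (ok_arc(j, i)) {
        add <- tibble::tibble(source = nodes[j], target = nodes[i], weight = w)
      }
      arcs <- dplyr::bind_rows(arcs, add)
    }
  }
  if (is.null(arcs) || ncol(arcs) == 0)
    arcs <- tibble::tibble(source = character(0), target = character(0),
                           weight = numeric(0))
  flow_network(arcs, var_classes, provenance = provenance)
}

#' Subnetwork driving a set of outflow signals
#'
#' Backtracks through the directed network: keeps modules with a directed
#' edge into any listed outflow, then inflows (and upstream modules) with a
#' directed path into any kept module, and returns the induced subgraph on
#' the kept nodes plus the listed outflows.
#'
#' @param network A [flow_network()].
#' @param outflow_subset Character vector of outflow variable names.
#' @return A [flow_network()] restricted to the drivers.
#' @export
extract_outflow_drivers <- function(network, outflow_subset) {
  unknown <- setdiff(outflow_subset, network$nodes)
  if (length(unknown))
    abort(paste0("unknown outflow(s): ", paste(unknown, collapse = ", ")))
  arcs <- network$arcs
  keep_mod <- unique(arcs$source[arcs$target %in% outflow_subset &
                                   network$var_class[arcs$source] == "module"])
  # reverse reachability into the kept modules
  frontier <- keep_mod
  kept <- keep_mod
  while (length(frontier)) {
    pre <- unique(arcs$source[arcs$target %in% frontier])
    pre <- setdiff(pre, kept)
    kept <- c(kept, pre)
    frontier <- pre[network$var_class[pre] == "module"]
  }
  nodes <- unique(c(kept, outflow_subset))
  sub <- arcs[arcs$source %in% nodes & arcs$target %in% nodes &
                (arcs$target %in% outflow_subset |
                   network$var_class[arcs$target] != "outflow"), ]
  flow_network(sub, network$var_class[names(network$var_class) %in% nodes],
               provenance = network$provenance)
}

#' Rank inflow signals by total edge frequency
#'
#' Scores each inflow node by the sum of bootstrap weights over its outgoing
#' arcs (configurably, the unweighted out-degree); descending order, ties
#' broken lexicographically.
#'
#' @param network A [flow_network()].
#' @param weighted Use bootstrap weights (default) or plain out-degree.
#' @return Tibble: `inflow`, `score`, `rank`.
#' @export
rank_inflow_drivers <- function(network, weighted = TRUE) {
  infl <- names(network$var_class)[network$var_class == "inflow"]
  sc <- vapply(infl, function(v) {
    rows <- network$arcs$source == v
    if (weighted) sum(network$arcs$weight[rows]) else sum(rows)
  }, numeric(1))
  tb <- tibble::tibble(inflow = infl, score = unname(sc)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$inflow)
  tb$rank <- seq_len(nrow(tb))
  tb
}

#' Ready-made learners for [bootstrap_learn()]
#'
#' `learner_gsp()` ignores condition labels and runs [gsp()];
#' `learner_ut_igsp()` treats `control` as the observational condition and
#' every other condition as a perturbed setting for [ut_igsp()].
#'
#' @param alpha_ci,alpha_inv Test levels.
#' @param n_restarts,dfs_depth Search settings, see [gsp()].
#' @param control Control condition label (ut_igsp only).
#' @return A function `(data, cond, seed)` returning a [cpdag_result()].
#' @export
learner_gsp <- function(alpha_ci = 0.05, n_restarts = 10, dfs_depth = 4) {
  function(data, cond = NULL, seed = NULL) {
    gsp(data, ci_tester_fisher_z(data, alpha_ci),
        n_restarts = n_restarts, dfs_depth = dfs_depth, seed = seed)
  }
}

#' @rdname learner_gsp
#' @export
learner_ut_igsp <- function(control, alpha_ci = 0.05, alpha_inv = 0.05,
                            n_restarts = 10, dfs_depth = 4) {
  function(data, cond, seed = NULL) {
    if (!control %in% cond) abort("control condition absent from data")
    ctrl <- data[cond == control, , drop = FALSE]
    others <- setdiff(unique(cond), control)
    settings <- lapply(others, function(cc) data[cond == cc, , drop = FALSE])
    names(settings) <- others
    ut_igsp(ctrl, settings, ci_tester_fisher_z(ctrl, alpha_ci),
            alpha_inv = alpha_inv, n_restarts = n_restarts,
            dfs_depth = dfs_depth, seed = seed)
  }
}
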