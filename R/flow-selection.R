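# Prioritizing informative flow variables: differential flows under a
# perturbation (Mann-Whitney U within each variable class) and spatially
# variable flows (graph-based global Moran's I).

#' Differentially flowing signal variables
#'
#' Runs a two-sided Mann-Whitney U (Wilcoxon rank-sum) test per variable of
#' the requested class between the control and perturbed condition, adjusts
#' p-values by Benjamini-Hochberg *within the class* (inflows and outflows
#' are always analyzed separately), and selects variables with adjusted
#' p below `p_adj_max` and |log2 fold change| above `lfc_min`. The fold
#' change is computed on expm1-scale condition means with pseudocount 1e-9.
#'
#' @param flowframe A [flow_frame()].
#' @param var_class `"inflow"` or `"outflow"`.
#' @param control,perturbed Condition labels to compare.
#' @param p_adj_max Adjusted-p threshold (default 0.05).
#' @param lfc_min |log2 FC| threshold (default 0.5).
#' @return Tibble: `variable`, `var_class`, `statistic`, `p`, `p_adj`,
#'   `log2fc`, `selected`.
#' @export
differential_flow_test <- function(flowframe, var_class = c("inflow", "outflow"),
                                   control, perturbed,
                                   p_adj_max = 0.05, lfc_min = 0.5) {
  var_class <- match.arg(var_class)
  cond <- flowframe$condition
  if (!all(c(control, perturbed) %in% cond))
    abort("control/perturbed labels not found among conditions")
  vals <- flow_values(flowframe)
  vars <- names(var_classes(flowframe))[var_classes(flowframe) == var_class]
  if (!length(vars)) return(selection_tibble(character(0), var_class))
  a <- vals[cond == control, vars, drop = FALSE]
  b <- vals[cond == perturbed, vars, drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) abort("need >= 2 samples per condition")
  res <- purrr::map_dfr(vars, function(v) {
    wt <- suppressWarnings(wilcox.test(b[, v], a[, v], exact = FALSE))
    eps <- 1e-9
    lfc <- log2((mean(expm1(b[, v])) + eps) / (mean(expm1(a[, v])) + eps))
    tibble::tibble(variable = v, var_class = var_class,
                   statistic = unname(wt$statistic), p = wt$p.value,
                   log2fc = lfc)
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$selected <- res$p_adj < p_adj_max & abs(res$log2fc) > lfc_min
  res[c("variable", "var_class", "statistic", "p", "p_adj", "log2fc",
        "selected")]
}

selection_tibble <- function(vars, var_class) {
  tibble::tibble(variable = vars, var_class = var_class,
                 statistic = numeric(0), p = numeric(0), p_adj = numeric(0),
                 log2fc = numeric(0), selected = logical(0))
}

#' Build a spatial neighborhood graph
#'
#' Symmetric binary weights from either mutual/union-symmetrized k-nearest
#' neighbours or a Delaunay triangulation (which falls back to knn with a
#' warning on degenerate, e.g. collinear, geometry).
#'
#' @param dataset A spatial [expression_dataset()] (or a coordinate matrix).
#' @param method `"knn"` or `"delaunay"`.
#' @param k Number of neighbours for knn (default 6).
#' @return A `spatial_graph`: list with `nodes`, symmetric 0/1 `weights`, and
#'   construction metadata.
#' @export
build_spatial_graph <- function(dataset, method = c("knn", "delaunay"), k = 6) {
  method <- match.arg(method)
  coords <- if (inherits(dataset, "expression_dataset")) {
    if (!dataset$spatial) abort("dataset has no spatial coordinates")
    dataset$coords
  } else as.matrix(dataset)
  n <- nrow(coords)
  if (n < 3) abort("need at least 3 spots")
  ids <- rownames(coords) %||% paste0("s", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  if (method == "delaunay") {
    edges <- tryCatch(delaunay_edges(coords), error = function(e) NULL)
    if (is.null(edges)) {
      warn("degenerate geometry for Delaunay triangulation; falling back to knn")
      method <- "knn"
    } else {
      W[edges] <- 1
      W[edges[, c(2, 1), drop = FALSE]] <- 1
    }
  }
  if (method == "knn") {
    k <- min(k, n - 1)
    d <- as.matrix(dist(coords))
    diag(d) <- Inf
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[seq_len(k)]
      W[i, nb] <- 1
      W[nb, i] <- 1
    }
  }
  diag(W) <- 0
  structure(list(nodes = ids, weights = W,
                 meta = list(method = method, k = if (method == "knn") k else NA)),
            class = "spatial_graph")
}

delaunay_edges <- function(coords) {
  if (!requireNamespace("deldir", quietly = TRUE))
    stop("deldir not available")
  if (nrow(unique(round(coords, 12))) < 3) stop("degenerate")
  # collinearity check: zero-area bounding triangle
  cc <- sweep(coords, 2, colMeans(coords))
  if (svd(cc)$d[2] < 1e-10 * (svd(cc)$d[1] + 1e-300)) stop("collinear")
  dd <- deldir::deldir(coords[, 1], coords[, 2], suppressMsge = TRUE)
  cbind(dd$delsgs$ind1, dd$delsgs$ind2)
}

#' Graph-based global Moran's I with a permutation null
#'
#' `I = (N / sum(w)) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centered
#' values z. The p-value comes from random permutations of the values over
#' the graph nodes (upper tail: positive autocorrelation). A constant field
#' returns `I = 0`, `p = 1`, flagged degenerate.
#'
#' @param values Named numeric vector over the graph nodes.
#' @param graph A `spatial_graph` from [build_spatial_graph()].
#' @param n_permutations Number of permutations (default 999).
#' @param seed Optional seed for the permutation null.
#' @return One-row tibble: `I`, `p`, `degenerate`.
#' @export
morans_i <- function(values, graph, n_permutations = 999, seed = NULL) {
  if (!is.null(names(values))) values <- values[graph$nodes]
  if (anyNA(values)) abort("values must cover every graph node")
  W <- graph$weights
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) {
    return(tibble::tibble(I = 0, p = 1, degenerate = TRUE))
  }
  s0 <- sum(W)
  n <- length(z)
  I_of <- function(zz) (n / s0) * drop(crossprod(zz, W %*% zz)) / sum(zz^2)
  I_obs <- I_of(z)
  perm <- with_seed(seed, replicate(n_permutations, I_of(z[sample.int(n)])))
  p <- (1 + sum(perm >= I_obs)) / (n_permutations + 1)
  tibble::tibble(I = I_obs, p = p, degenerate = FALSE)
}

#' Spatially variable flow variables
#'
#' Retains variables whose global Moran's I exceeds `i_min` and (when
#' permutations are used) whose BH-adjusted permutation p is below
#' `p_adj_max`.
#'
#' @param flowframe A [flow_frame()].
#' @param graph A `spatial_graph` whose nodes match the samples.
#' @param i_min Moran's I threshold (default 0.1).
#' @param n_permutations Permutations per variable; 0 disables the p filter.
#' @param p_adj_max Adjusted-p threshold when permutations are used.
#' @param seed Optional seed.
#' @return Tibble: `variable`, `var_class`, `statistic` (I), `p`, `p_adj`,
#'   `selected`.
#' @export
select_spatially_variable <- function(flowframe, graph, i_min = 0.1,
                                      n_permutations = 999, p_adj_max = 0.05,
                                      seed = NULL) {
  vals <- flow_values(flowframe)
  vc <- var_classes(flowframe)
  res <- purrr::map_dfr(colnames(vals), function(v) {
    mi <- morans_i(setNames(vals[, v], rownames(vals)), graph,
                   n_permutations = max(n_permutations, 1), seed = seed)
    tibble::tibble(variable = v, var_class = unname(vc[v]),
                   statistic = mi$I, p = mi$p)
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$selected <- res$statistic > i_min &
    (n_permutations == 0 | res$p_adj < p_adj_max)
  res
}
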