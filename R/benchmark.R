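# Scoring inferred networks against scenario ground truth, and the benchmark
# grid over inflow measurement and data modes.

#' True positive and true negative rates against a ground-truth scenario
#'
#' Over the ordered node pairs of the scenario node set:
#' TPR = (true arcs recovered with exact direction) / (true arcs);
#' TNR = (ordered pairs with neither a true nor an inferred arc) /
#' (ordered pairs with no true arc). An undirected CPDAG edge counts as an
#' inferred arc in both directions.
#'
#' @param inferred A [flow_network()] or [cpdag_result()] over the scenario
#'   nodes.
#' @param truth A [scenario_truth()] object.
#' @return One-row tibble: `tpr`, `tnr`, `n_true`, `n_negative`.
#' @export
evaluate_tpr_tnr <- function(inferred, truth) {
  nodes <- truth$nodes
  inf_arcs <- inferred_arc_matrix(inferred, nodes)
  true_m <- amat_from_arcs(nodes, truth$arcs$from, truth$arcs$to)
  off <- !diag(length(nodes))
  tp <- sum(inf_arcs & true_m)
  n_true <- sum(true_m)
  neg <- off & !true_m
  tn <- sum(neg & !inf_arcs)
  tibble::tibble(tpr = tp / n_true, tnr = tn / sum(neg),
                 n_true = n_true, n_negative = sum(neg))
}

inferred_arc_matrix <- function(inferred, nodes) {
  if (inherits(inferred, "flow_network")) {
    miss <- setdiff(nodes, names(inferred$var_class))
    if (length(miss))
      abort(paste0("network does not cover node(s): ",
                   paste(miss, collapse = ", ")))
    amat_from_arcs(nodes, inferred$arcs$source, inferred$arcs$target)
  } else if (inherits(inferred, "cpdag_result")) {
    miss <- setdiff(nodes, inferred$nodes)
    if (length(miss))
      abort(paste0("graph does not cover node(s): ",
                   paste(miss, collapse = ", ")))
    inferred$amat[nodes, nodes]  # undirected edges already symmetric
  } else abort("`inferred` must be a flow_network or cpdag_result")
}

#' Default benchmark settings grid
#'
#' The two-by-two grid of the synthetic validation: inflow measured as the
#' bound ligand-receptor complex versus total receptor expression (free plus
#' bound), crossed with control-only versus control-plus-perturbation data.
#'
#' @param flow_model_applied Whether the biological flow model constrains the
#'   result (recycled across rows).
#' @return Tibble with columns `inflow_mode`, `data_mode`,
#'   `flow_model_applied`.
#' @export
benchmark_settings_grid <- function(flow_model_applied = TRUE) {
  tidyr::expand_grid(
    inflow_mode = c("total_receptor", "bound_receptor"),
    data_mode = c("control_only", "control_plus_perturbation"),
    flow_model_applied = flow_model_applied
  )
}

#' Run the synthetic benchmark for one scenario
#'
#' For every replicate and grid setting: simulate control (and perturbed)
#' cells, assemble the learning matrix over the scenario nodes with the
#' requested inflow measurement (log1p-transformed), learn the structure with
#' [gsp()] (control only) or [ut_igsp()] (control plus perturbation),
#' optionally apply the biological flow model, and score TPR/TNR against the
#' ground truth.
#'
#' @param scenario_id Scenario name, see [scenario_truth()].
#' @param n_replicates Number of independent replicates (default 500).
#' @param settings_grid Tibble from [benchmark_settings_grid()] (default full
#'   two-by-two grid with the flow model applied).
#' @param n_cells Cells per condition (default 500).
#' @param n_restarts,dfs_depth,alpha_ci,alpha_inv Learner settings.
#' @param seed Master seed; replicate r derives its own seeds from it.
#' @return A `flow_benchmark` tibble: one row per replicate x setting with
#'   `tpr` and `tnr`, carrying the scenario id as an attribute.
#' @export
run_benchmark <- function(scenario_id, n_replicates = 500,
                          settings_grid = benchmark_settings_grid(),
                          n_cells = 500, n_restarts = 10, dfs_depth = 4,
                          alpha_ci = 0.05, alpha_inv = 0.05, seed = 1) {
  truth <- scenario_truth(scenario_id)
  need_pert <- any(settings_grid$data_mode == "control_plus_perturbation")
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    seed_r <- seed + 7919L * r
    ctrl <- simulate_scenario(truth, n_cells, "control", seed = seed_r)
    pert <- if (need_pert)
      simulate_scenario(truth, n_cells, "perturbed", seed = seed_r + 1L)
    rows[[r]] <- purrr::pmap_dfr(settings_grid, function(inflow_mode,
                                                         data_mode,
                                                         flow_model_applied) {
      res <- benchmark_one(truth, ctrl, pert, inflow_mode, data_mode,
                           flow_model_applied, n_restarts, dfs_depth,
                           alpha_ci, alpha_inv, seed_r)
      tibble::tibble(replicate = r, inflow_mode = inflow_mode,
                     data_mode = data_mode,
                     flow_model_applied = flow_model_applied,
                     tpr = res$tpr, tnr = res$tnr)
    })
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "scenario") <- scenario_id
  class(out) <- c("flow_benchmark", class(out))
  out
}

# One replicate x setting: build node matrices, learn, orient, score.
benchmark_one <- function(truth, ctrl, pert, inflow_mode, data_mode,
                          flow_model_applied, n_restarts, dfs_depth,
                          alpha_ci, alpha_inv, seed_r) {
  take <- function(sim) {
    m <- sim[, truth$nodes, drop = FALSE]
    if (inflow_mode == "total_receptor") {
      for (cx in names(truth$receptors)) {
        m[, cx] <- sim[, paste0(truth$receptors[[cx]]$free, ".total")]
      }
    }
    log1p(m)
  }
  xc <- take(ctrl)
  cp <- if (data_mode == "control_plus_perturbation") {
    ut_igsp(xc, list(perturbed = take(pert)),
            ci_tester_fisher_z(xc, alpha_ci), alpha_inv = alpha_inv,
            n_restarts = n_restarts, dfs_depth = dfs_depth, seed = seed_r)
  } else {
    gsp(xc, ci_tester_fisher_z(xc, alpha_ci), n_restarts = n_restarts,
        dfs_depth = dfs_depth, seed = seed_r)
  }
  inferred <- if (flow_model_applied) apply_flow_model(cp, truth$var_class)
              else cp
  evaluate_tpr_tnr(inferred, truth)
}

#' Quartile summary of a benchmark run
#'
#' @param x A `flow_benchmark` tibble from [run_benchmark()].
#' @param ... Unused.
#' @return Tibble of min/Q1/median/Q3/max for TPR and TNR per setting.
#' @export
glance.flow_benchmark <- function(x, ...) {
  dplyr::group_by(x, .data$inflow_mode, .data$data_mode,
                  .data$flow_model_applied) |>
    dplyr::summarise(
      dplyr::across(c("tpr", "tnr"),
                    list(min = min,
                         q1 = ~unname(quantile(.x, 0.25)),
                         median = median,
                         q3 = ~unname(quantile(.x, 0.75)),
                         max = max),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    )
}

#' Box plots of benchmark TPR/TNR by setting
#'
#' @param object A `flow_benchmark` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_benchmark <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("tpr", "tnr"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$data_mode, y = .data$value,
                               fill = .data$inflow_mode)) +
    ggplot2::geom_boxplot(outlier.shape = 18, position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_manual(values = c(bound_receptor = "#1f4e9c",
                                          total_receptor = "#9ecbff")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "inflow",
                  title = attr(object, "scenario")) +
    ggplot2::theme_bw()
}
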