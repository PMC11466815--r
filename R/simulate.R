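# Kinetic sampling of the benchmark scenarios and a generic linear-Gaussian
# SEM sampler used to test the structure learners.

hill_act <- function(x, K, n) x^n / (K^n + x^n)
hill_rep <- function(x, K, n) K^n / (K^n + x^n)

#' Simulate cells from a benchmark scenario
#'
#' Per cell: exogenous ligand and free-receptor abundances are drawn
#' log-normally; the bound complex forms by mass-action saturation without
#' receptor depletion, `C = R_free * L / (K_b * exp(eta) + L)` (noise acts on
#' the binding affinity), and total receptor is free plus bound; downstream nodes
#' follow Hill activation/repression of their parents with independent
#' multiplicative log-normal structural noise, solved to steady state by
#' damped fixed-point iteration when the circuit contains feedback. The
#' perturbed condition multiplies the driving ligand's production rate.
#'
#' @param truth A [scenario_truth()] object.
#' @param n_cells Number of cells (>= 10).
#' @param condition `"control"` or `"perturbed"`.
#' @param seed Integer seed.
#' @param on_cycle `"average"` (default) reports cycle-average expression for
#'   cells on a limit cycle of the regulatory dynamics; `"error"` enforces a
#'   strict steady-state contract and fails on sustained oscillation.
#' @return Numeric matrix, cells x (scenario nodes + one `<free>.total`
#'   column per receptor carrying free-plus-bound expression).
#' @export
simulate_scenario <- function(truth, n_cells = 500,
                              condition = c("control", "perturbed"),
                              seed = NULL, on_cycle = c("average", "error")) {
  condition <- match.arg(condition)
  truth$on_cycle <- match.arg(on_cycle)
  if (n_cells < 10) abort("need at least 10 cells")
  kin <- truth$kinetics
  with_seed(seed, {
    exo <- function(prod = 1) prod * rlnorm(n_cells, 0, kin$exo_sd)
    eta <- function() rlnorm(n_cells, 0, kin$noise_sd)
    cols <- list()
    # ligand-receptor binding per inflow node
    for (cx in names(truth$receptors)) {
      rc <- truth$receptors[[cx]]
      prod <- 1
      if (condition == "perturbed" && rc$ligand == truth$perturbation$ligand)
        prod <- truth$perturbation$multiplier
      L <- exo(prod)
      Rfree <- exo(1)  # free receptor pool, no depletion by binding
      C <- Rfree * L / (kin$K_bind * eta() + L)
      cols[[rc$ligand]] <- L
      cols[[cx]] <- C
      cols[[rc$free]] <- Rfree
      cols[[paste0(rc$free, ".total")]] <- Rfree + C
    }
    downstream <- simulate_downstream(truth, cols, eta)
    cols <- c(cols, downstream)
    out <- do.call(cbind, cols[c(truth$nodes,
                                 paste0(vapply(truth$receptors, `[[`, "",
                                               "free"), ".total"))])
    rownames(out) <- paste0(condition, "_", seq_len(n_cells))
    out
  })
}

# Steady state of the downstream (module/outflow) nodes given the complexes.
# Production of each node is the product of Hill terms over its parents,
# times its structural noise factor; degradation is 1, so the steady state
# equals production. Feedback circuits are solved by damped iteration.
simulate_downstream <- function(truth, cols, eta) {
  kin <- truth$kinetics
  made <- names(cols)
  todo <- setdiff(truth$nodes, made)
  if (!length(todo)) return(list())
  n <- length(cols[[1]])
  noise <- lapply(todo, function(nd) eta())
  names(noise) <- todo
  half_max <- function(from, to) {
    if (truth$id == "shh_bmp_competition" && from == "r-SHH" &&
        to == "GEM-I") kin$K_intermediate else kin$K
  }
  # precompute parent structure; exogenous regulators contribute fixed factors
  plan <- lapply(todo, function(nd) {
    pa <- truth$arcs[truth$arcs$to == nd, ]
    fixed <- rep(kin$production, n) * noise[[nd]]
    dyn <- list()
    for (r in seq_len(nrow(pa))) {
      src <- pa$from[r]; sgn <- pa$sign[r]; K <- half_max(src, nd)
      if (src %in% names(cols)) {
        fixed <- fixed * if (sgn == "+") hill_act(cols[[src]], K, kin$hill_n)
                         else hill_rep(cols[[src]], K, kin$hill_n)
      } else {
        dyn[[length(dyn) + 1L]] <- list(src = src, act = sgn == "+", K = K)
      }
    }
    list(fixed = fixed, dyn = dyn)
  })
  names(plan) <- todo
  hn <- kin$hill_n
  production <- function(state) {
    lapply(plan, function(pl) {
      v <- pl$fixed
      for (d in pl$dyn) {
        xn <- state[[d$src]]^hn
        Kn <- d$K^hn
        v <- v * (if (d$act) xn else Kn) / (Kn + xn)
      }
      v
    })
  }
  state <- setNames(rep(list(rep(kin$K, n)), length(todo)), todo)
  has_feedback <- any(truth$arcs$from %in% todo & truth$arcs$to %in% todo &
                        truth$arcs$from != truth$arcs$to)
  if (!has_feedback) {
    for (it in 1:3) state <- production(state)
    return(state)
  }
  # Relaxation dynamics dx/dt = f(x) - x, explicit Euler to a fixed horizon.
  # Cross-repression circuits can be bistable or (with an odd repression
  # cycle) genuinely oscillatory; cells on a limit cycle are reported as
  # their cycle-average expression, the phase-marginal a transcriptomic
  # snapshot measures. `on_cycle = "error"` restores a strict steady-state
  # contract.
  dt <- 0.1; t_total <- 40; t_avg <- 10
  n_steps <- round(t_total / dt)
  avg_from <- n_steps - round(t_avg / dt) + 1L
  acc <- setNames(rep(list(rep(0, n)), length(todo)), todo)
  n_acc <- 0L
  delta <- Inf
  for (it in seq_len(n_steps)) {
    nxt <- production(state)
    delta <- max(vapply(todo, function(nd)
      max(abs(nxt[[nd]] - state[[nd]])), numeric(1)))
    if (!is.finite(delta) ||
        max(vapply(state, max, numeric(1))) > 1e6) {
      abort(sprintf(
        "dynamics diverged (scenario %s, K = %g, hill n = %g)",
        truth$id, kin$K, kin$hill_n))
    }
    state <- setNames(lapply(todo, function(nd)
      state[[nd]] + dt * (nxt[[nd]] - state[[nd]])), todo)
    if (delta < 1e-10) break
    if (it >= avg_from) {
      acc <- setNames(lapply(todo, function(nd)
        acc[[nd]] + state[[nd]]), todo)
      n_acc <- n_acc + 1L
    }
  }
  if (delta >= 1e-10) {
    if (identical(truth$on_cycle %||% "average", "error")) {
      abort(sprintf(
        "steady state did not converge (scenario %s, K = %g, hill n = %g): oscillation",
        truth$id, kin$K, kin$hill_n))
    }
    state <- setNames(lapply(acc, function(v) v / n_acc), names(acc))
  }
  state
}

#' Sample from a linear-Gaussian structural equation model
#'
#' Ancestral sampling in topological order: each node is the weighted sum of
#' its parents plus Gaussian noise. Supports per-node mean-shift
#' interventions.
#'
#' @param dag Logical adjacency matrix of the DAG.
#' @param weights Numeric matrix of edge weights (same shape; ignored where
#'   `dag` is FALSE), or a single number used for every edge.
#' @param noise_sd Noise standard deviation (scalar or per-node).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param shift Optional named numeric vector of mean shifts (an
#'   intervention on those nodes).
#' @return Numeric samples-by-nodes matrix.
#' @export
sample_linear_gaussian_sem <- function(dag, weights = 1, noise_sd = 1, n,
                                       seed = NULL, shift = NULL) {
  p <- ncol(dag)
  nodes <- colnames(dag) %||% paste0("V", seq_len(p))
  if (length(weights) == 1) weights <- matrix(weights, p, p)
  noise_sd <- rep_len(noise_sd, p)
  ord <- topological_order(dag)
  with_seed(seed, {
    x <- matrix(0, n, p, dimnames = list(NULL, nodes))
    for (j in ord) {
      pa <- which(dag[, j] & !dag[j, ])
      mu <- if (length(pa)) x[, pa, drop = FALSE] %*% weights[pa, j] else 0
      x[, j] <- mu + rnorm(n, 0, noise_sd[j])
      if (!is.null(shift) && nodes[j] %in% names(shift))
        x[, j] <- x[, j] + shift[[nodes[j]]]
    }
    x
  })
}
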