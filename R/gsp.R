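# Permutation-based causal structure learning: minimal IMAPs, the greedy
# sparsest permutation (GSP) search over covered-edge reversals, and its
# unknown-target interventional extension that scores conditional invariance
# across perturbed settings.

#' Minimal IMAP DAG of a variable ordering
#'
#' For an ordering pi, places an arc pi\[a\] -> pi\[b\] (a < b) exactly when
#' pi\[a\] and pi\[b\] are dependent given the remaining earlier variables.
#' The result is acyclic by construction and is an independence map of the
#' tested conditional-independence relations.
#'
#' @param data Samples-by-variables matrix (may be `NULL` when `ci_tester`
#'   carries its own sufficient statistic or oracle graph).
#' @param permutation Integer vector or character vector of variable names.
#' @param ci_tester A tester from [ci_tester_fisher_z()] or
#'   [ci_tester_dsep()]; defaults to Fisher-z on `data` at level 0.05.
#' @return Logical adjacency matrix of the DAG.
#' @export
minimal_imap_dag <- function(data, permutation, ci_tester = NULL) {
  if (is.null(ci_tester)) ci_tester <- ci_tester_fisher_z(data)
  nodes <- imap_nodes(data, ci_tester)
  perm <- if (is.character(permutation)) match(permutation, nodes)
          else as.integer(permutation)
  if (anyNA(perm) || !setequal(perm, seq_along(nodes)))
    abort("`permutation` must order all variables exactly once")
  if (identical(ci_tester$kind, "fisher_z")) {
    a <- .imap_perm_fisher_z(ci_tester$suffstat$C, ci_tester$suffstat$n,
                             ci_tester$alpha, perm)
    dimnames(a) <- list(nodes, nodes)
    return(a)
  }
  p <- length(perm)
  amat <- empty_amat(nodes)
  for (b in seq_len(p)[-1]) {
    prefix <- perm[seq_len(b - 1L)]
    for (a in seq_len(b - 1L)) {
      S <- setdiff(prefix, perm[a])
      if (ci_tester$test(perm[a], perm[b], S)) amat[perm[a], perm[b]] <- TRUE
    }
  }
  amat
}

imap_nodes <- function(data, ci_tester) {
  if (identical(ci_tester$kind, "fisher_z")) return(ci_tester$suffstat$names)
  if (identical(ci_tester$kind, "dsep")) return(colnames(ci_tester$dag))
  if (!is.null(data)) return(colnames(as.matrix(data)))
  abort("cannot determine variable names")
}

covered_edges <- function(amat) {
  # i -> j is covered iff pa(j) = pa(i) u {i}; reversing keeps acyclicity.
  idx <- which(amat & !t(amat), arr.ind = TRUE)
  if (!nrow(idx)) return(idx)
  keep <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    setequal(parents_of(amat, j), c(parents_of(amat, i), i))
  }, logical(1))
  idx[keep, , drop = FALSE]
}

# Depth-first greedy descent over covered-edge reversals shared by gsp() and
# ut_igsp(). `score_fn(perm)` returns list(score, dag); lower scores are
# better; equal-score moves are explored up to `dfs_depth`.
gsp_descend <- function(perm, score_fn, dfs_depth) {
  cur <- score_fn(perm)
  cur$perm <- perm
  repeat {
    visited <- new.env(parent = emptyenv())
    visited[[paste(cur$perm, collapse = ".")]] <- TRUE
    found <- gsp_dfs(cur, score_fn, 0L, dfs_depth, visited)
    if (is.null(found)) break
    cur <- found
  }
  cur
}

gsp_dfs <- function(cur, score_fn, depth, max_depth, visited) {
  ce <- covered_edges(cur$dag)
  if (!nrow(ce)) return(NULL)
  ord <- order(ce[, 1], ce[, 2])
  for (r in ord) {
    g2 <- cur$dag
    i <- ce[r, 1]; j <- ce[r, 2]
    g2[i, j] <- FALSE; g2[j, i] <- TRUE
    perm2 <- topological_order(g2)
    key <- paste(perm2, collapse = ".")
    if (!is.null(visited[[key]])) next
    visited[[key]] <- TRUE
    cand <- score_fn(perm2)
    cand$perm <- perm2
    if (cand$score < cur$score) return(cand)
    if (cand$score == cur$score && depth < max_depth) {
      deeper <- gsp_dfs(cand, score_fn, depth + 1L, max_depth, visited)
      if (!is.null(deeper)) return(deeper)
    }
  }
  NULL
}

#' Greedy sparsest permutation (GSP) structure learning
#'
#' From each random starting ordering, builds the minimal IMAP, then greedily
#' traverses covered-edge reversals (depth-first up to `dfs_depth` through
#' equally sparse neighbours) accepting strictly sparser minimal IMAPs until a
#' local optimum; returns the CPDAG of the sparsest DAG over all restarts.
#'
#' @inheritParams minimal_imap_dag
#' @param n_restarts Number of random starting permutations (the first restart
#'   always uses the natural column order).
#' @param dfs_depth Maximum depth of equal-score depth-first exploration.
#' @param seed Integer seed controlling the restarts.
#' @return A [cpdag_result()].
#' @export
gsp <- function(data, ci_tester = NULL, n_restarts = 10, dfs_depth = 4,
                seed = NULL) {
  if (is.null(ci_tester)) ci_tester <- ci_tester_fisher_z(data)
  nodes <- imap_nodes(data, ci_tester)
  if (length(nodes) < 2) abort("need at least 2 variables")
  score_fn <- make_imap_scorer(data, ci_tester)
  best <- run_restarts(nodes, score_fn, n_restarts, dfs_depth, seed)
  cpdag_from_dag(best$dag)
}

make_imap_scorer <- function(data, ci_tester, inv_tester = NULL) {
  cache <- new.env(parent = emptyenv())
  function(perm) {
    key <- paste(perm, collapse = ".")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    dag <- minimal_imap_dag(data, perm, ci_tester)
    score <- sum(dag)
    if (!is.null(inv_tester)) {
      for (k in seq_len(inv_tester$n_settings)) {
        for (b in seq_along(perm)) {
          S <- if (b == 1) integer(0) else perm[seq_len(b - 1L)]
          if (!inv_tester$invariant(perm[b], S, k)) score <- score + 1L
        }
      }
    }
    out <- list(score = score, dag = dag)
    cache[[key]] <- out
    out
  }
}

run_restarts <- function(nodes, score_fn, n_restarts, dfs_depth, seed) {
  p <- length(nodes)
  perms <- with_seed(seed, c(
    list(seq_len(p)),
    replicate(max(0, n_restarts - 1), sample.int(p), simplify = FALSE)
  ))
  best <- NULL
  for (perm in perms) {
    res <- gsp_descend(perm, score_fn, dfs_depth)
    if (is.null(best) || res$score < best$score) best <- res
  }
  best
}

#' Interventional GSP with unknown intervention targets (UT-IGSP)
#'
#' Extends [gsp()] to one or more perturbed conditions whose intervention
#' targets are unknown. A permutation's score adds, to the number of IMAP
#' edges on the control data, the number of (setting, variable) pairs whose
#' conditional distribution given the earlier variables fails the Gaussian
#' invariance test — the sparsest joint explanation of dependence and
#' mechanism change. Estimated targets and the invariance pattern also orient
#' edges beyond the observational Markov equivalence class, via completion of
#' the DAG augmented with one indicator node per perturbed setting.
#'
#' @param control_data Control-condition matrix (samples x variables).
#' @param perturbed_datasets List of perturbed-condition matrices with the
#'   same columns.
#' @param ci_tester Optional CI tester on the control data.
#' @param invariance_tester Optional invariance tester; defaults to
#'   [invariance_tester_gauss()] at level `alpha_inv`.
#' @param alpha_inv Invariance-test level when building the default tester.
#' @inheritParams gsp
#' @return A [cpdag_result()] with `$targets`, the estimated intervention
#'   targets per perturbed dataset.
#' @export
ut_igsp <- function(control_data, perturbed_datasets, ci_tester = NULL,
                    invariance_tester = NULL, n_restarts = 10, dfs_depth = 4,
                    alpha_inv = 0.05, seed = NULL) {
  if (length(perturbed_datasets) == 0) {
    warn("no perturbed datasets supplied; falling back to gsp()")
    return(gsp(control_data, ci_tester, n_restarts, dfs_depth, seed))
  }
  if (is.null(ci_tester)) ci_tester <- ci_tester_fisher_z(control_data)
  if (is.null(invariance_tester)) {
    invariance_tester <- invariance_tester_gauss(control_data,
                                                 perturbed_datasets, alpha_inv)
  }
  nodes <- imap_nodes(control_data, ci_tester)
  score_fn <- make_imap_scorer(control_data, ci_tester, invariance_tester)
  best <- run_restarts(nodes, score_fn, n_restarts, dfs_depth, seed)
  dag <- best$dag
  targets <- lapply(seq_len(invariance_tester$n_settings), function(k) {
    hit <- vapply(seq_along(nodes), function(i) {
      !invariance_tester$invariant(i, parents_of(dag, i), k)
    }, logical(1))
    nodes[hit]
  })
  names(targets) <- names(perturbed_datasets) %||%
    paste0("setting", seq_along(targets))
  res <- cpdag_augmented(dag, targets)
  res$targets <- targets
  res
}

# CPDAG of a DAG augmented with per-setting indicator nodes pointing at the
# estimated targets; indicator arcs stay directed and their v-structures or
# Meek propagation orient additional variable edges. Indicators are stripped
# from the returned graph.
cpdag_augmented <- function(dag, targets) {
  nodes <- colnames(dag)
  zeta <- paste0(".zeta", seq_along(targets))
  aug_nodes <- c(zeta, nodes)
  aug <- empty_amat(aug_nodes)
  aug[nodes, nodes] <- dag
  forced <- empty_amat(aug_nodes)
  for (k in seq_along(targets)) {
    tgt <- targets[[k]]
    aug[zeta[k], tgt] <- TRUE
    forced[zeta[k], tgt] <- TRUE
  }
  cp <- cpdag_from_dag(aug, forced = forced)
  cpdag_result(cp$amat[nodes, nodes])
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
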